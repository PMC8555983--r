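# Plain-text table formats. Lineage tables and frame tables are
# tab-separated with a header; times in minutes (absolute from experiment
# start), lengths in micrometres. Focus positions within a frame are
# semicolon-separated relative positions z/L in [0, 1].

LINEAGE_REQUIRED_COLS <- c("cell_id", "parent_id", "t_birth_min", "t_div_min",
                           "L0_um", "Ld_um")

#' Read a lineage table
#'
#' @param path Path to a TSV with at least the columns `cell_id`,
#'   `parent_id`, `t_birth_min`, `t_div_min`, `L0_um`, `Ld_um`; optional
#'   columns (`condition_id`, `L0_sibling_um`, `mu_per_min`, latent
#'   simulator fields) are preserved. Extra columns are allowed.
#' @return A tibble of cell-cycle records.
#' @export
read_lineages <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE)
  missing <- setdiff(LINEAGE_REQUIRED_COLS, names(tab))
  if (length(missing) > 0) {
    stop("lineage table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(tab$t_div_min <= tab$t_birth_min)) {
    stop("lineage table has t_div <= t_birth", call. = FALSE)
  }
  if (any(tab$L0_um <= 0) || any(tab$Ld_um <= 0)) {
    stop("lineage table has non-positive lengths", call. = FALSE)
  }
  tibble::as_tibble(tab)
}

#' Write a lineage table
#'
#' @param lineages A lineage tibble (see [read_lineages()] for the schema).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_lineages <- function(lineages, path) {
  write_tsv_plain(as.data.frame(lineages), path)
}

#' Read a per-frame trace table
#'
#' @param path Path to a TSV with columns `cell_id`, `t_min`, `L_um`,
#'   `Itot` and `focus_rel_positions` (semicolon-separated z/L values;
#'   empty string for no focus).
#' @return A tibble of frames.
#' @export
read_frames <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE,
                           colClasses = c(focus_rel_positions = "character"))
  required <- c("cell_id", "t_min", "L_um", "Itot", "focus_rel_positions")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("frame table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tab$focus_rel_positions[is.na(tab$focus_rel_positions)] <- ""
  tibble::as_tibble(tab)
}

#' Write a per-frame trace table
#'
#' @param frames A frames tibble (see [read_frames()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_frames <- function(frames, path) {
  write_tsv_plain(as.data.frame(frames), path)
}

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Split semicolon-separated focus positions into numeric vectors
#'
#' @param x Character vector like `"0.25;0.75"`.
#' @return A list of numeric vectors (empty for no foci).
#' @export
parse_focus_positions <- function(x) {
  lapply(strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE),
         function(v) as.numeric(v[nzchar(v)]))
}
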