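#' Read a phosphopeptide quantification table
#'
#' Tab-separated, UTF-8, with header columns `protein_id`, `site`,
#' `model_id`, `timepoint`, `replicate`, `disease_signal`, `control_signal`.
#' Lines starting with `#` are skipped. A `ratio` column may replace the two
#' signal columns, in which case the control signal is set to 1.
#'
#' @param path File path.
#' @return Data frame of quantification records.
#' @export
read_quant_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8")
  key <- c("protein_id", "site", "model_id", "timepoint", "replicate")
  missing_cols <- setdiff(key, names(tab))
  if (length(missing_cols) > 0L)
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  if (!all(c("disease_signal", "control_signal") %in% names(tab))) {
    if (!"ratio" %in% names(tab))
      stop("need disease_signal/control_signal or ratio columns")
    tab$disease_signal <- tab$ratio
    tab$control_signal <- 1
  }
  dup <- duplicated(tab[key])
  if (any(dup))
    stop(sprintf("duplicate record for %s %s (model %s, timepoint %s, replicate %s)",
                 tab$protein_id[dup][1L], tab$site[dup][1L],
                 tab$model_id[dup][1L], tab$timepoint[dup][1L],
                 tab$replicate[dup][1L]))
  tab
}

#' Write a tab-separated table
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a network in SIF format
#'
#' Simple interaction format: one `a pp b` line per edge, isolated nodes as
#' bare-name lines.
#'
#' @param nodes Character vector of node names.
#' @param edges Data frame with columns `a`, `b`.
#' @param path Output path.
#' @param relation Interaction label, default `"pp"`.
#' @return `path`, invisibly.
#' @export
write_sif <- function(nodes, edges, path, relation = "pp") {
  lines <- character(0)
  if (nrow(edges) > 0L)
    lines <- paste(edges$a, relation, edges$b)
  isolated <- setdiff(nodes, c(edges$a, edges$b))
  writeLines(c(lines, isolated), path)
  invisible(path)
}
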