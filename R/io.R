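# Delimited-text readers/writers for campaign tables.
# Single tabular dialect: comma-separated, header row, UTF-8, '.' decimal.

campaign_schema <- c("condition_id", "batch", "t_fill_mm", "t_in_die_mm",
                     "tablet", "W_mg", "F_punch_kN", "H_tablet_mm",
                     "hardness_N")

#' Read and write tableting campaign tables
#'
#' A campaign file has one row per tablet with columns `condition_id`,
#' `batch`, `t_fill_mm`, `t_in_die_mm`, `tablet`, `W_mg`, `F_punch_kN`,
#' `H_tablet_mm`, `hardness_N`. Reading validates the schema and rejects
#' non-numeric cells and non-positive weights with row-numbered messages;
#' `write_campaign()` followed by `read_campaign()` is the identity.
#'
#' @param path File path.
#'
#' @return `read_campaign()`: a validated campaign tibble.
#' @export
read_campaign <- function(path) {
  if (!file.exists(path)) stop_domain(sprintf("No such file: %s", path))
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_double()))
  missing <- setdiff(campaign_schema, names(out))
  if (length(missing)) {
    stop_domain(sprintf("Campaign file lacks columns: %s",
                        paste(missing, collapse = ", ")))
  }
  probs <- readr::problems(out)
  if (nrow(probs)) {
    stop_domain(sprintf(
      "Non-numeric cells in campaign file (first at line %d, column %d).",
      probs$row[1] + 1L, probs$col[1]
    ))
  }
  bad <- which(!is.finite(out$W_mg) | out$W_mg <= 0)
  if (length(bad)) {
    stop_domain(sprintf(
      "Non-positive tablet weight at data row(s) %s.",
      paste(head(bad, 5), collapse = ", ")
    ))
  }
  out$condition_id <- as.integer(out$condition_id)
  out$batch <- as.integer(out$batch)
  out$tablet <- as.integer(out$tablet)
  out
}

#' @rdname read_campaign
#' @param campaign A campaign tibble (see [simulate_campaign()]).
#' @return `write_campaign()`: the input, invisibly.
#' @export
write_campaign <- function(campaign, path) {
  missing <- setdiff(campaign_schema, names(campaign))
  if (length(missing)) {
    stop_domain(sprintf("Campaign table lacks columns: %s",
                        paste(missing, collapse = ", ")))
  }
  readr::write_csv(campaign[campaign_schema], path)
  invisible(campaign)
}
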