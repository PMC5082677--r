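#' @title Published study tables as data fixtures
#' @description
#' The four printed tables of the original study ship as version-controlled
#' CSVs with checksums, so the classification stage can be exercised against
#' the published numbers: substratum coverage per strain at inoculation and
#' after ten days (`table2`), the mean aggregated architecture quantities per
#' operator (`table3`), their cross-strain rescaled values, i.e. the
#' colonization indices (`table4`), and the five-strain selection used for
#' the porous/intermediate/compact characterization (`table5`).
#' @name fixtures
NULL

.fixture_md5 <- c(
  table2 = "a25aacb06249add10480d4d6044cac20",
  table3 = "62541c979697cb728aae257034f48c86",
  table4 = "96005938d7a5c2e4ea5a3a00f148081b",
  table5 = "e2300b2adc3b035e7d267900a7b20f44")

#' Load a printed study table
#'
#' @param identifier one of `"table2"`, `"table3"`, `"table4"`, `"table5"`.
#' @return A data frame keyed by `strain` with the columns as printed:
#'   `t0`/`t10` coverage percentages plus the surviving-strain flag for
#'   `table2`; per-operator values (`max`, `average`, `weighted`) for
#'   `table3`--`table5`. The identifier is kept in attribute `"identifier"`.
#' @examples
#' t5 <- load_fixture("table5")
#' t5[t5$strain == "Nostoc commune", ]
#' @export
load_fixture <- function(identifier) {
  if (length(identifier) != 1L || !identifier %in% names(.fixture_md5))
    stop("unknown fixture identifier; use one of ",
         paste(names(.fixture_md5), collapse = ", "))
  path <- system.file("extdata", paste0(identifier, ".csv"),
                      package = "biofilmarch", mustWork = TRUE)
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, unname(.fixture_md5[identifier])))
    stop("fixture ", identifier, " failed its checksum; the packaged CSV ",
         "was modified")
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  attr(out, "identifier") <- identifier
  out
}

#' Classify strains from a printed index table
#'
#' Applies [classify_strain()] to each row of the colonization-index fixture
#' (`table4` or `table5`): the three per-operator values of a row are the
#' strain's colonization indices. Also summarizes the index range per label
#' group and per operator column.
#'
#' @param fixture a data frame from [load_fixture()] (`table4` or `table5`),
#'   or an identifier string.
#' @return A list with `labels` (data frame: strain, per-operator labels,
#'   majority label, unanimity flag) and `group_summary` (data frame of
#'   min/max index per majority label and operator).
#' @export
classify_from_fixture <- function(fixture) {
  if (is.character(fixture)) fixture <- load_fixture(fixture)
  ops <- c("max", "average", "weighted")
  if (!all(c("strain", ops) %in% names(fixture)))
    stop("fixture must carry per-operator colonization indices ",
         "(columns max, average, weighted)")
  rows <- lapply(seq_len(nrow(fixture)), function(i) {
    ic <- stats::setNames(as.numeric(fixture[i, ops]), ops)
    cl <- classify_strain(ic)
    data.frame(strain = fixture$strain[i],
               label_max = cl$per_operator[["max"]],
               label_average = cl$per_operator[["average"]],
               label_weighted = cl$per_operator[["weighted"]],
               label = cl$label, unanimous = cl$unanimous)
  })
  labels <- do.call(rbind, rows)
  summ <- list()
  for (lab in unique(labels$label)) for (op in ops) {
    v <- fixture[[op]][labels$label == lab]
    summ[[length(summ) + 1L]] <- data.frame(
      label = lab, operator = op, n = length(v),
      min_index = min(v), max_index = max(v))
  }
  list(labels = labels, group_summary = do.call(rbind, summ))
}
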