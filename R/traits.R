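#' Derive the seven damage trait definitions from raw 0-3 scores
#'
#' Raw ear (`ED03`) and tail (`TD03`) damage are scored 0 (no damage) to 3
#' (severe damage). Five derived definitions are recomputed from these raw
#' scores (existing derived columns are overwritten, so the raw scores stay
#' the single source of truth):
#' \describe{
#'   \item{ED01, TD01}{binary versions, 1 if any damage}
#'   \item{AD01}{any damage on either body part}
#'   \item{NBP}{number of body parts affected, 0-2}
#'   \item{SD06}{sum of the raw scores, 0-6}
#' }
#'
#' @param table a data frame with integer columns `ED03` and `TD03` in 0..3.
#' @return the table with columns `ED01`, `TD01`, `AD01`, `NBP`, `SD06`
#'   populated. Idempotent.
#' @export
derive_traits <- function(table) {
  for (col in c("ED03", "TD03")) {
    if (!col %in% names(table)) stop("column '", col, "' is missing")
    x <- table[[col]]
    bad <- which(is.na(x) | x != as.integer(x) | x < 0 | x > 3)
    if (length(bad))
      stop("out-of-range ", col, " score in row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "))
  }
  ed <- as.integer(table$ED03)
  td <- as.integer(table$TD03)
  table$ED01 <- as.integer(ed > 0L)
  table$TD01 <- as.integer(td > 0L)
  table$AD01 <- pmax(table$ED01, table$TD01)
  table$NBP <- table$ED01 + table$TD01
  table$SD06 <- ed + td
  table
}

#' Names of the seven damage trait definitions
#' @export
damage_traits <- function() c("ED03", "ED01", "TD03", "TD01", "AD01", "NBP", "SD06")
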