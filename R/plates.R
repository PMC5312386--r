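#' Construct and validate a plate set
#'
#' A plate set holds grid-addressed raw signals from 384-well viability
#' screens in long format: one record per well and induction condition.
#' Rows are indexed 1-16 (letters A-P accepted), columns 1-24. Well types
#' are `"sample"` (library siRNA pools), `"control"` or `"empty"`.
#'
#' @param x data.frame with columns `plate`, `row`, `col`, `gene`,
#'   `well_type`, `condition`, `signal`. `row` may be letters A-P or
#'   integers 1-16; `signal` must be finite and positive for non-empty
#'   wells.
#' @return A `plate_set`: the validated data.frame with integer row/col.
#' @examples
#' df <- data.frame(plate = "P1", row = rep(1:16, each = 24),
#'                  col = rep(1:24, 16), gene = paste0("g", 1:384),
#'                  well_type = "sample", condition = "uninduced",
#'                  signal = 1000)
#' ps <- plate_set(df)
#' @export
plate_set <- function(x) {
  needed <- c("plate", "row", "col", "gene", "well_type", "condition", "signal")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols))
    stop("plate set is missing columns: ", paste(missing_cols, collapse = ", "))
  x <- as.data.frame(x)[needed]
  if (is.character(x$row) || is.factor(x$row)) {
    rw <- as.character(x$row)
    letter <- rw %in% LETTERS[1:16]
    rw[letter] <- match(rw[letter], LETTERS[1:16])
    x$row <- suppressWarnings(as.integer(rw))
  }
  x$row <- as.integer(x$row)
  x$col <- as.integer(x$col)
  if (anyNA(x$row) || any(x$row < 1L | x$row > 16L))
    stop("plate rows must be 1-16 or letters A-P")
  if (anyNA(x$col) || any(x$col < 1L | x$col > 24L))
    stop("plate columns must be 1-24")
  if (!all(x$well_type %in% c("sample", "control", "empty")))
    stop("well_type must be one of 'sample', 'control', 'empty'")
  key <- paste(x$plate, x$row, x$col, x$condition, sep = "\r")
  if (anyDuplicated(key)) {
    d <- x[duplicated(key), , drop = FALSE][1, ]
    stop(sprintf("duplicate well address: plate %s row %d col %d condition %s",
                 d$plate, d$row, d$col, d$condition))
  }
  nonempty <- x$well_type != "empty"
  if (any(!is.finite(x$signal[nonempty]) | x$signal[nonempty] <= 0))
    stop("raw signal must be finite and > 0 for all non-empty wells")
  n_sample <- tapply(x$well_type == "sample", x$plate, sum)
  if (any(n_sample < 1))
    stop("every plate needs at least one sample well; offending plate(s): ",
         paste(names(n_sample)[n_sample < 1], collapse = ", "))
  class(x) <- c("plate_set", "data.frame")
  x
}

#' Read a long-format screen CSV
#'
#' Expected header: `plate,row,col,gene,well_type,condition,signal`.
#'
#' @param path file path.
#' @return A [plate_set()].
#' @export
read_screen_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  plate_set(x)
}

#' Write a plate set as long-format CSV
#'
#' @param x a [plate_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_screen_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
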