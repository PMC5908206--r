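#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

matrix_to_pairs <- function(m, value_name = "value") {
  ut <- which(upper.tri(m), arr.ind = TRUE)
  out <- tibble::tibble(i = ut[, 1], j = ut[, 2], value = m[ut])
  names(out)[3] <- value_name
  out
}

#' Tidy a coactivation matrix into one row per node pair
#'
#' @param x A `ser_coactivation`.
#' @param ... Unused.
#' @return Tibble with columns `i`, `j`, `coactivation` (upper-triangle
#'   pairs).
#' @export
tidy.ser_coactivation <- function(x, ...) {
  matrix_to_pairs(x$values, "coactivation")
}

#' @rdname tidy.ser_coactivation
#' @export
glance.ser_coactivation <- function(x, ...) {
  off <- offdiag(x$values)
  tibble::tibble(
    n_nodes = nrow(x$values), runs = x$runs, steps = x$steps,
    mean_coactivation = mean(off), max_coactivation = max(off)
  )
}

#' Tidy a prediction matrix into one row per node pair
#'
#' @param x A `ser_prediction`.
#' @param ... Unused.
#' @return Tibble with columns `i`, `j`, `predicted`, `predictor`.
#' @export
tidy.ser_prediction <- function(x, ...) {
  out <- matrix_to_pairs(x$values, "predicted")
  out$predictor <- x$predictor
  out
}

#' Tidy a motif inventory into long form
#'
#' One row per (class, location) with the count, matching the long-form
#' export `(i, j, class, k, l, count)`.
#'
#' @param x A `ser_motif_inventory`.
#' @param ... Unused.
#' @return Tibble with columns `i`, `j`, `class`, `k`, `l`, `count`.
#' @export
tidy.ser_motif_inventory <- function(x, ...) {
  i <- x$pair[["i"]]; j <- x$pair[["j"]]
  row <- function(class, k, l, count) {
    tibble::tibble(i = i, j = j, class = class,
                   k = as.integer(k), l = as.integer(l),
                   count = as.integer(count))
  }
  out <- list(
    row("t0", NA, NA, x$t0),
    row("t00_i", NA, NA, x$t00_i),
    row("t00_j", NA, NA, x$t00_j),
    row("t02", NA, NA, x$t02),
    row("t13", NA, NA, x$t13)
  )
  for (k in names(x$t01_i)) out <- c(out, list(row("t01_i", k, NA, x$t01_i[[k]])))
  for (k in names(x$t01_j)) out <- c(out, list(row("t01_j", k, NA, x$t01_j[[k]])))
  for (k in names(x$t11)) out <- c(out, list(row("t11", k, NA, x$t11[[k]])))
  for (key in names(x$t12)) {
    kl <- as.integer(strsplit(key, "-")[[1]])
    out <- c(out, list(row("t12", kl[1], kl[2], x$t12[[key]])))
  }
  dplyr::bind_rows(out)
}
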