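#' @importFrom rlang .data abort warn
#' @importFrom stats sd setNames
NULL

# cell_type codes treated as non-neuronal pseudo-cells / excludable targets
.pseudo_types <- c("muscle", "basal-lamina", "space")

# exclusion keyword -> predicate over the roster rows of post targets
.exclusion_keys <- c("bm", "Ep", "Mu", "space")

exclusion_mask <- function(keys, roster_rows) {
  bad <- setdiff(keys, .exclusion_keys)
  if (length(bad) > 0) {
    abort(paste0("unknown exclusion keyword(s): ", paste(bad, collapse = ", "),
                 " (allowed: ", paste(.exclusion_keys, collapse = ", "), ")"))
  }
  drop <- rep(FALSE, nrow(roster_rows))
  if ("bm" %in% keys)    drop <- drop | roster_rows$cell_type == "basal-lamina"
  if ("Ep" %in% keys)    drop <- drop | roster_rows$cell_type == "ependymal"
  if ("Mu" %in% keys)    drop <- drop | roster_rows$cell_type == "muscle" |
                                        roster_rows$region == "muscle"
  if ("space" %in% keys) drop <- drop | roster_rows$cell_type == "space"
  drop
}

#' Round a pair of counts to percentages that sum to 100
#'
#' Largest-remainder rounding of `100 * counts / sum(counts)` so the printed
#' pair always sums to exactly 100, as in conventional left:right ratio
#' tables.
#'
#' @param counts numeric vector of non-negative counts (length >= 2).
#' @param digits integer, decimal places of the result (default 0).
#' @return numeric vector of percentages summing to 100.
#' @export
largest_remainder_pct <- function(counts, digits = 0) {
  stopifnot(length(counts) >= 2, all(counts >= 0), sum(counts) > 0)
  scale <- 10^digits
  exact <- 100 * counts / sum(counts)
  lower <- floor(exact * scale)
  short <- round(100 * scale - sum(lower))
  rem <- exact * scale - lower
  add <- rep(0, length(counts))
  if (short > 0) {
    take <- order(rem, decreasing = TRUE)[seq_len(short)]
    add[take] <- 1
  }
  (lower + add) / scale
}

# population SD (divisor n); divisor_n = FALSE gives the sample SD
pop_sd <- function(x, divisor_n = TRUE) {
  n <- length(x)
  if (n == 0) return(NA_real_)
  if (divisor_n) sqrt(sum((x - mean(x))^2) / n) else sd(x)
}
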