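#' Generate a Box-Behnken design
#'
#' Builds the three-level Box-Behnken layout for `k` factors: for every
#' unordered factor pair the four (-1, +1) combinations are run with all
#' other factors held at 0, followed by `n_center` all-zero center
#' replicates. For `k` factors the edge portion has `4 * choose(k, 2)`
#' runs and each factor is away from 0 in exactly `4 * (k - 1)` of them.
#' With four factors and five centers this is the classical 29-run
#' design.
#'
#' Run order is deterministic: pair blocks in lexicographic factor-pair
#' order, the (-1,-1), (-1,+1), (+1,-1), (+1,+1) combinations within a
#' block, and center points last. Supply `seed` to randomize the row
#' order reproducibly (the set of runs is unchanged).
#'
#' @param factors A factor tibble from [rsm_factors()] with 3 to 7 rows.
#' @param n_center Number of replicated center points (>= 1).
#' @param seed Optional integer; if given, rows are randomly permuted
#'   under this seed.
#' @return A tibble with columns `run`, one coded column per factor
#'   symbol, one actual column per factor name, and logical `center`.
#' @examples
#' fct <- fyn22_factors()
#' bbd_design(fct, n_center = 5)
#' @export
bbd_design <- function(factors, n_center = 5, seed = NULL) {
  validate_factors(factors)
  k <- nrow(factors)
  if (k < 3 || k > 7) {
    rlang::abort("Box-Behnken designs are generated for 3 to 7 factors",
                 class = "fermrsm_unsupported_design")
  }
  if (n_center < 1) {
    rlang::abort("at least one center point is required",
                 class = "fermrsm_unsupported_design")
  }
  pairs <- utils::combn(k, 2)
  blocks <- lapply(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1, p]; j <- pairs[2, p]
    m <- matrix(0, nrow = 4, ncol = k)
    m[, i] <- c(-1, -1, 1, 1)
    m[, j] <- c(-1, 1, -1, 1)
    m
  })
  runs <- rbind(do.call(rbind, blocks), matrix(0, nrow = n_center, ncol = k))
  colnames(runs) <- factors$symbol
  out <- tibble::as_tibble(runs)
  out <- tibble::add_column(out, run = seq_len(nrow(out)), .before = 1)
  if (!is.null(seed)) {
    perm <- withr_seed(seed, sample.int(nrow(out)))
    out <- out[perm, ]
    out$run <- seq_len(nrow(out))
  }
  out <- decode_runs(out, factors)
  out$center <- rowSums(abs(out[factors$symbol])) == 0
  out
}

# evaluate expr under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Validate a Box-Behnken run table
#'
#' Checks the defining invariants of the layout: every non-center run
#' has exactly two factors at +/-1 and the rest at 0, coded columns are
#' balanced (sum 0) with sum of squares `4 * (k - 1)`, and the run count
#' is `4 * choose(k, 2) + n_center`.
#'
#' @param design A design tibble as returned by [bbd_design()].
#' @param factors The factor tibble the design was built from.
#' @return `design`, invisibly; aborts with class
#'   `fermrsm_invalid_design` if an invariant fails.
#' @export
validate_bbd <- function(design, factors) {
  validate_factors(factors)
  k <- nrow(factors)
  m <- as.matrix(design[factors$symbol])
  centers <- rowSums(abs(m)) == 0
  edge <- m[!centers, , drop = FALSE]
  ok_edge <- all(rowSums(edge != 0) == 2) && all(edge %in% c(-1, 0, 1))
  ok_count <- nrow(m) == 4 * choose(k, 2) + sum(centers)
  ok_balance <- all(colSums(m) == 0) && all(colSums(m^2) == 4 * (k - 1))
  if (!(ok_edge && ok_count && ok_balance)) {
    rlang::abort("run table is not a Box-Behnken layout",
                 class = "fermrsm_invalid_design")
  }
  invisible(design)
}

#' Pick the best factor level from a one-factor-at-a-time screen
#'
#' Returns the level whose mean response is largest, the rule used to
#' center the design region on the winners of a one-factor-at-a-time
#' (OFAT) screen. Ties are broken toward the lowest level (the cheapest
#' medium).
#'
#' @param data A data frame with one row per tested level.
#' @param level Column of tested levels (tidy-eval).
#' @param response Column of mean responses (tidy-eval).
#' @return One-row tibble with the winning `level` and `response`.
#' @examples
#' ofat <- tibble::tibble(starch = c(0.8, 1.0, 1.2, 1.4),
#'                        spores = c(4.1, 5.0, 5.39, 5.1))
#' select_best_level(ofat, starch, spores)
#' @export
select_best_level <- function(data, level, response) {
  data <- tibble::as_tibble(data)
  lev <- dplyr::pull(data, {{ level }})
  resp <- dplyr::pull(data, {{ response }})
  if (length(lev) == 0) {
    rlang::abort("no levels supplied", class = "fermrsm_empty_input")
  }
  stopifnot(length(lev) == length(resp))
  winners <- which(resp == max(resp))
  best <- winners[which.min(lev[winners])]
  tibble::tibble(level = lev[best], response = resp[best])
}
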