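# Derive independent L'Ecuyer-CMRG RNG streams from one master seed.
# Returns a list of .Random.seed states, one per stream; callers assign
# a state to the global RNG before simulating so that grid cells are
# reproducible and order-independent.
.rng_streams <- function(seed, n_streams) {
  old_kind <- RNGkind()
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    RNGkind(old_kind[1L], old_kind[2L], old_kind[3L])
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  RNGkind("L'Ecuyer-CMRG")
  set.seed(as.integer(seed %% 2147483647))
  s <- get(".Random.seed", envir = globalenv())
  streams <- vector("list", n_streams)
  for (i in seq_len(n_streams)) {
    streams[[i]] <- s
    s <- parallel::nextRNGStream(s)
  }
  streams
}

.set_rng_state <- function(state) {
  assign(".Random.seed", state, envir = globalenv())
}

#' Select the best-powered trait's rejection vector
#'
#' Single-trait power is conventionally summarized by the trait with the
#' largest rejection fraction.  Given a replicate-by-trait rejection
#' matrix, returns the rejection vector of the trait whose rejection
#' fraction is maximal, ties broken toward the lowest trait index.
#'
#' @param rejections Logical (or 0/1) matrix, replicates in rows, traits
#'   in columns.
#' @return Logical vector of length `nrow(rejections)`, with the chosen
#'   trait index as attribute `trait`.
#' @export
best_trait_selection <- function(rejections) {
  rejections <- as.matrix(rejections)
  pw <- colMeans(rejections)
  j <- which.max(pw)  # which.max returns the first maximum
  structure(as.logical(rejections[, j]), trait = j)
}

#' Paired binomial exact comparison of two methods' power
#'
#' Over matched replicates, let `S1` and `S2` be the numbers of
#' rejections by methods 1 and 2 and `N_m = S1 + S2`.  Conditionally on
#' `N_m`, `S1` is binomial(`N_m`, p) with `p = 1/2` when the methods are
#' equally powerful.  If `S1 > N_m / 2` the one-sided exact test of
#' `H0: p <= 1/2` is performed (rejection means method 1 is
#' significantly more powerful); if `S1 < N_m / 2`, the opposite
#' one-sided test.
#'
#' @param M1,M2 Equal-length binary rejection vectors.
#' @param alpha Significance level for the `significant` flag.
#' @return List with `S1`, `S2`, `N_m`, `p_value`, `direction` (one of
#'   `"M1_more_powerful"`, `"M2_more_powerful"`, `"no_difference"`) and
#'   `significant`.
#' @export
binomial_power_comparison <- function(M1, M2, alpha = 0.05) {
  M1 <- as.integer(as.logical(M1)); M2 <- as.integer(as.logical(M2))
  if (length(M1) != length(M2)) stop("M1 and M2 must have equal length")
  S1 <- sum(M1); S2 <- sum(M2); Nm <- S1 + S2
  if (Nm == 0L)
    return(list(S1 = 0L, S2 = 0L, N_m = 0L, p_value = 1,
                direction = "no_difference", significant = FALSE))
  if (S1 > Nm / 2) {
    p <- stats::pbinom(S1 - 1L, Nm, 0.5, lower.tail = FALSE)  # P(X >= S1)
    dir <- "M1_more_powerful"
  } else if (S1 < Nm / 2) {
    p <- stats::pbinom(S1, Nm, 0.5)                           # P(X <= S1)
    dir <- "M2_more_powerful"
  } else {
    p <- 1
    dir <- "no_difference"
  }
  list(S1 = S1, S2 = S2, N_m = Nm, p_value = p, direction = dir,
       significant = (dir != "no_difference") && p <= alpha)
}

# One simulated dataset analysed by every requested method/model.
# Returns a named logical vector of rejections plus per-trait vectors
# for the single-trait comparators.
.analyse_dataset <- function(dataset, models, alpha, theta) {
  tt <- dataset$traits
  marker <- dataset$marker
  m <- ncol(tt)
  s <- standardize(tt)
  cs <- select_canonical(eigendecompose(s), s, theta = theta)
  monomorphic <- length(unique(marker)) < 2L
  out <- list(k = cs$k)
  for (mod in models) {
    if (monomorphic) {
      out[[paste0("pcbmr_", mod)]] <- FALSE
      out[[paste0("st_", mod)]] <- rep(FALSE, m)
      out[[paste0("stb_", mod)]] <- rep(FALSE, m)
      next
    }
    md <- encode_genotype(marker, mod)
    res <- pcbmr_test(cs, md)
    out[[paste0("pcbmr_", mod)]] <- !res$degenerate && res$p_value <= alpha
    pj <- vapply(seq_len(m), function(j) {
      fit <- .lrt_deviance(unclass(tt)[, j], md)
      if (fit$degenerate) 1 else stats::pchisq(fit$stat, fit$df, lower.tail = FALSE)
    }, numeric(1))
    out[[paste0("st_", mod)]] <- pj <= alpha
    out[[paste0("stb_", mod)]] <- pj <= alpha / m
  }
  out
}

#' Monte-Carlo type-I error and power over a scenario grid
#'
#' For each grid value (effect `b`, LD `r`, or trait count, depending on
#' the scenario) simulates `reps` datasets and records the rejection
#' fraction at level `alpha` for the pleiotropy test (PCBMR) and the
#' single-trait comparators without (SATN) and with (SATB) Bonferroni
#' adjustment, under each requested genetic model.  Single-trait cells
#' report the trait with the largest rejection fraction, selected by
#' [best_trait_selection()].  Each grid cell draws from its own RNG
#' stream derived from `seed`, so results do not depend on cell order.
#'
#' @param scenario Integer 1-4.
#' @param grid Numeric vector of grid values: effect `b` for scenarios 1
#'   and 3, LD correlation `r` for scenario 2, trait counts for
#'   scenario 4.
#' @param reps Replicate datasets per grid value.
#' @param alpha Rejection level (default 0.05).
#' @param models Genetic models to evaluate.
#' @param n Subjects per dataset (default 100).
#' @param theta Variance-explained threshold for canonical selection.
#' @param seed Master seed.
#' @return Object of class `power_grid`: a data frame with columns
#'   `scenario`, `grid`, `method`, `model`, `reps`, `n`, `rejections`,
#'   `power`, `mc_se`, `k_mode`, plus an attribute `rejection_vectors`
#'   (nested list `[[grid]][[model]]` with logical `pcbmr`, `satn`,
#'   `satb` replicate vectors) for paired power comparisons.
#' @export
run_power_grid <- function(scenario, grid, reps,
                           alpha = 0.05,
                           models = c("GEN", "ADD", "DOM", "REC"),
                           n = 100L, theta = 0.8, seed = 1L) {
  if (reps < 1L) stop("reps must be at least 1")
  models <- match.arg(toupper(models), c("GEN", "ADD", "DOM", "REC"),
                      several.ok = TRUE)
  streams <- .rng_streams(seed, length(grid))
  old_kind <- RNGkind()
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    RNGkind(old_kind[1L], old_kind[2L], old_kind[3L])
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  RNGkind("L'Ecuyer-CMRG")
  rows <- list()
  rej_all <- list()
  for (g in seq_along(grid)) {
    .set_rng_state(streams[[g]])
    cfg <- switch(as.character(scenario),
      "1" = scenario_config(1L, n = n, b = grid[g]),
      "2" = scenario_config(2L, n = n, r = grid[g]),
      "3" = scenario_config(3L, n = n, b = grid[g]),
      "4" = scenario_config(4L, n = n, n_traits = grid[g]),
      stop("scenario must be 1, 2, 3 or 4"))
    m <- cfg$n_traits
    pc <- matrix(FALSE, reps, length(models), dimnames = list(NULL, models))
    st <- lapply(models, function(mod) matrix(FALSE, reps, m))
    stb <- lapply(models, function(mod) matrix(FALSE, reps, m))
    names(st) <- names(stb) <- models
    kk <- integer(reps)
    for (rep in seq_len(reps)) {
      ds <- simulate_scenario(cfg)
      a <- .analyse_dataset(ds, models, alpha, theta)
      kk[rep] <- a$k
      for (mod in models) {
        pc[rep, mod] <- a[[paste0("pcbmr_", mod)]]
        st[[mod]][rep, ] <- a[[paste0("st_", mod)]]
        stb[[mod]][rep, ] <- a[[paste0("stb_", mod)]]
      }
    }
    rej_g <- list()
    for (mod in models) {
      satn_vec <- best_trait_selection(st[[mod]])
      satb_vec <- best_trait_selection(stb[[mod]])
      rej_g[[mod]] <- list(pcbmr = pc[, mod], satn = satn_vec, satb = satb_vec,
                           satn_by_trait = st[[mod]], satb_by_trait = stb[[mod]])
      for (method in c("PCBMR", "SATN", "SATB")) {
        v <- switch(method, PCBMR = pc[, mod], SATN = satn_vec, SATB = satb_vec)
        pw <- mean(v)
        rows[[length(rows) + 1L]] <- data.frame(
          scenario = scenario, grid = grid[g], method = method, model = mod,
          reps = reps, n = n, rejections = sum(v), power = pw,
          mc_se = sqrt(pw * (1 - pw) / reps),
          k_mode = as.integer(names(sort(table(kk), decreasing = TRUE))[1L]))
      }
    }
    rej_all[[as.character(grid[g])]] <- rej_g
  }
  out <- do.call(rbind, rows)
  attr(out, "rejection_vectors") <- rej_all
  attr(out, "seed") <- seed
  class(out) <- c("power_grid", "data.frame")
  out
}

#' Annotate a power grid with paired binomial comparisons
#'
#' Adds, for every grid value and model, the paired exact binomial
#' comparison of PCBMR against SATN and against SATB (method 1 is always
#' PCBMR), using the stored replicate-level rejection vectors.
#'
#' @param grid_result A [run_power_grid()] result.
#' @param alpha Significance level of the comparison (default 0.05).
#' @return Data frame: `grid`, `model`, `comparison`, `S1`, `S2`,
#'   `p_value`, `direction`, `significant`.
#' @export
compare_methods <- function(grid_result, alpha = 0.05) {
  rv <- attr(grid_result, "rejection_vectors")
  rows <- list()
  for (g in names(rv)) {
    for (mod in names(rv[[g]])) {
      r <- rv[[g]][[mod]]
      for (other in c("satn", "satb")) {
        cmp <- binomial_power_comparison(r$pcbmr, r[[other]], alpha = alpha)
        rows[[length(rows) + 1L]] <- data.frame(
          grid = as.numeric(g), model = mod,
          comparison = paste0("PCBMR_vs_", toupper(other)),
          S1 = cmp$S1, S2 = cmp$S2, p_value = cmp$p_value,
          direction = cmp$direction, significant = cmp$significant)
      }
    }
  }
  do.call(rbind, rows)
}
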