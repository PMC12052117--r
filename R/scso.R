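#' Sand cat swarm optimization configuration
#'
#' @param n_agents Population size N (>= 2).
#' @param max_iter Maximum iteration count T (>= 0; 0 returns the best of
#'   the initial random population).
#' @param bounds Numeric matrix with 2 rows (`low`, `high`) and one column
#'   per dimension, or a length-2 vector for a 1-D problem.
#' @param sensitivity_max Sensitivity ceiling sM (default 2, mirroring the
#'   sand cat's 0-2 kHz hearing range); the general sensitivity rG decays
#'   linearly from sM to 0 over the iterations.
#' @param seed Integer seed; identical config and seed give an identical
#'   trace.
#' @param explore_form Exploration update form: `"additive"` (default)
#'   uses `r * (x_best + rand * x_i)`; `"subtractive"` is the classical
#'   SCSO variant `r * (x_best - rand * x_i)`.
#' @return Object of class `scso_config`.
#' @export
scso_config <- function(n_agents = 30, max_iter = 100, bounds,
                        sensitivity_max = 2, seed = 1L,
                        explore_form = c("additive", "subtractive")) {
  explore_form <- match.arg(explore_form)
  if (is.vector(bounds) && length(bounds) == 2) bounds <- matrix(bounds, 2, 1)
  bounds <- as.matrix(bounds)
  if (nrow(bounds) != 2 || any(bounds[1, ] >= bounds[2, ])) {
    stop("bounds must be a 2 x D matrix with low < high per dimension")
  }
  if (n_agents < 2) stop("n_agents must be >= 2")
  if (max_iter < 0) stop("max_iter must be >= 0")
  structure(
    list(n_agents = as.integer(n_agents), max_iter = as.integer(max_iter),
         bounds = bounds, sensitivity_max = sensitivity_max,
         seed = as.integer(seed), explore_form = explore_form),
    class = "scso_config"
  )
}

#' Minimize a bounded continuous function by sand cat swarm optimization
#'
#' Population metaheuristic alternating prey search (exploration) and prey
#' attack (exploitation). Per iteration the general sensitivity decays
#' linearly, `rG = sM * (1 - t/T)`; each agent draws a transition control
#' `R ~ U(-rG, rG)` and a sensitivity `r = rG * u`. With `|R| <= 1` the
#' agent attacks: `P = |u' * x_best - x_i|` and
#' `x_i <- x_best - r * P * cos(theta)` with the angle theta drawn by an
#' equal-weight roulette wheel over 0..360 degrees; otherwise it searches
#' (see `explore_form`). Positions are clipped to the bounds after every
#' update and the best-so-far fitness trace is non-increasing by
#' construction.
#'
#' @param fitness Function mapping a numeric vector (length D) to a scalar;
#'   non-finite values are treated as `+Inf`.
#' @param cfg An [scso_config()].
#' @return List with `x_best`, `f_best`, `history` (best fitness after
#'   initialization and after each iteration), and `trace` (data.frame of
#'   iteration, best_fitness, best position).
#' @export
scso_minimize <- function(fitness, cfg) {
  stopifnot(inherits(cfg, "scso_config"))
  lo <- cfg$bounds[1, ]; hi <- cfg$bounds[2, ]
  D <- length(lo); N <- cfg$n_agents; T <- cfg$max_iter
  sM <- cfg$sensitivity_max
  eval_fit <- function(x) {
    v <- fitness(x)
    if (!is.finite(v)) Inf else v
  }
  with_seed(cfg$seed, {
    pos <- matrix(stats::runif(N * D, rep(lo, each = N), rep(hi, each = N)), N, D)
    fit <- apply(pos, 1, eval_fit)
    bi <- which.min(fit)
    x_best <- pos[bi, ]; f_best <- fit[bi]
    history <- f_best
    trace <- list(data.frame(iteration = 0L, best_fitness = f_best,
                             t(x_best)))
    if (T > 0) {
      for (t in 0:(T - 1)) {
        rG <- sM * (1 - t / T)
        for (i in seq_len(N)) {
          R <- stats::runif(1, -rG, rG)
          r <- rG * stats::runif(1)
          theta <- sample(0:360, 1) * pi / 180 # equal-weight roulette wheel
          if (abs(R) <= 1) { # attack the prey
            P <- abs(stats::runif(D) * x_best - pos[i, ])
            cand <- x_best - r * P * cos(theta)
          } else {           # search for prey
            u <- stats::runif(D)
            cand <- if (cfg$explore_form == "additive") {
              r * (x_best + u * pos[i, ])
            } else {
              r * (x_best - u * pos[i, ])
            }
          }
          cand <- pmin(pmax(cand, lo), hi)
          pos[i, ] <- cand
          fi <- eval_fit(cand)
          fit[i] <- fi
          if (fi < f_best) {
            f_best <- fi
            x_best <- cand
          }
        }
        history <- c(history, f_best)
        trace[[length(trace) + 1L]] <-
          data.frame(iteration = t + 1L, best_fitness = f_best, t(x_best))
      }
    }
    trace <- do.call(rbind, trace)
    names(trace)[-(1:2)] <- paste0("x", seq_len(D))
    list(x_best = x_best, f_best = f_best, history = history, trace = trace)
  })
}

#' Tune the pseudo-label weight by SCSO
#'
#' One-dimensional adapter: searches the pseudo-label weight `alpha` in
#' `[0, 1]` minimizing the supplied fitness (typically the validation loss
#' of the sequence classifier after a short weighted-training run).
#'
#' @param train_fn Function `alpha -> scalar fitness`; non-finite returns
#'   are treated as `+Inf`.
#' @param cfg An [scso_config()] with 1-D bounds inside `[0, 1]`; a default
#'   configuration is built when omitted.
#' @param seed Seed used when `cfg` is omitted.
#' @return List with `alpha`, `fitness`, `history` and `trace`.
#' @export
optimize_pseudo_weight <- function(train_fn, cfg = NULL, seed = 1L) {
  if (is.null(cfg)) {
    cfg <- scso_config(n_agents = 20, max_iter = 50, bounds = c(0, 1),
                       seed = seed)
  }
  if (ncol(cfg$bounds) != 1 || cfg$bounds[1, 1] < 0 || cfg$bounds[2, 1] > 1) {
    stop("pseudo-weight bounds must be one-dimensional within [0, 1]")
  }
  res <- scso_minimize(function(x) train_fn(x[1]), cfg)
  list(alpha = res$x_best[1], fitness = res$f_best,
       history = res$history, trace = res$trace)
}

#' Write an optimization trace CSV
#'
#' @param trace The `trace` data.frame from [scso_minimize()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_scso_trace <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}
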