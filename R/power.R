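# Monte-Carlo power simulation for a two-group M-value comparison with
# heavy-tailed (Student t) noise, and the sample-size multiplier search.

#' Specify the power simulation
#'
#' The simulation model is
#' `M_i = intercept + delta * X_i + sigma * T_i`, `T_i ~ t(df)`,
#' with `X_i = 1` for ART-conceived and 0 for naturally conceived subjects.
#' `sigma` multiplies the t variate, so the total noise SD is
#' `sigma * sqrt(df / (df - 2))` (about 0.548 at the defaults). Each
#' iteration tests the group coefficient of an ordinary least-squares fit
#' with a two-sided Wald test at level `alpha`; the default alpha is the
#' Bonferroni-corrected 0.05 / 25 = 0.002 for a 25-probe candidate family.
#'
#' @param n_natural,n_art group sizes (default: the study's cord-blood
#'   counts, 247 naturally conceived and 81 ART-conceived).
#' @param intercept baseline M-value (default 1.2).
#' @param delta true ART effect in M-value units (default 0.13).
#' @param sigma t-noise scale multiplier in M-value units (default 0.49).
#' @param df degrees of freedom of the t noise (default 10; must exceed 2
#'   for finite variance).
#' @param alpha two-sided significance level (default 0.002).
#' @param n_iter Monte-Carlo iterations (default 10000).
#' @param seed integer seed.
#' @return list of class `power_spec`.
#' @export
power_spec <- function(n_natural = 247L, n_art = 81L, intercept = 1.2,
                       delta = 0.13, sigma = 0.49, df = 10,
                       alpha = bonferroni_alpha(0.05, 25L),
                       n_iter = 10000L, seed = 1L) {
  stopifnot(sigma > 0, df > 2, alpha > 0, alpha < 1,
            n_natural >= 2L, n_art >= 2L, n_iter >= 1L)
  structure(list(n_natural = as.integer(n_natural), n_art = as.integer(n_art),
                 intercept = intercept, delta = delta, sigma = sigma,
                 df = df, alpha = alpha, n_iter = as.integer(n_iter),
                 seed = as.integer(seed)),
            class = "power_spec")
}

#' Monte-Carlo power of the two-group Wald test
#'
#' Simulates `n_iter` datasets under the [power_spec()] model and, per
#' iteration, applies the two-sided Wald test (normal reference) to the
#' group-difference coefficient of the ordinary least-squares fit — for a
#' two-group design this is the group-mean difference over its pooled-variance
#' standard error. Power is the fraction of iterations rejecting at `alpha`.
#'
#' @param spec a [power_spec()].
#' @return list of class `power_result`: `power`, `mc_se`
#'   (`sqrt(power * (1 - power) / n_iter)`), `n_rejections`, `n_total`
#'   (total subjects per iteration) and the `spec`.
#' @examples
#' simulate_power(power_spec(n_natural = 200, n_art = 100, n_iter = 500))
#' @export
simulate_power <- function(spec) {
  stopifnot(inherits(spec, "power_spec"))
  set.seed(spec$seed)
  n1 <- spec$n_natural
  n2 <- spec$n_art
  it <- spec$n_iter
  crit <- stats::qnorm(1 - spec$alpha / 2)

  # vectorized over iterations (columns are simulated datasets), in blocks
  # to bound memory at large n
  block <- max(1L, min(it, as.integer(2e7 %/% (n1 + n2))))
  n_rej <- 0L
  done <- 0L
  while (done < it) {
    b <- min(block, it - done)
    nat <- matrix(spec$intercept +
                    spec$sigma * stats::rt(n1 * b, df = spec$df),
                  nrow = n1, ncol = b)
    art <- matrix(spec$intercept + spec$delta +
                    spec$sigma * stats::rt(n2 * b, df = spec$df),
                  nrow = n2, ncol = b)
    m1 <- colMeans(nat)
    m2 <- colMeans(art)
    # pooled residual variance of the OLS fit, df = n - 2
    ss <- colSums(nat^2) - n1 * m1^2 + colSums(art^2) - n2 * m2^2
    s2 <- ss / (n1 + n2 - 2)
    se <- sqrt(s2 * (1 / n1 + 1 / n2))
    z <- (m2 - m1) / se
    n_rej <- n_rej + sum(abs(z) > crit)
    done <- done + b
  }
  power <- n_rej / it
  structure(list(power = power,
                 mc_se = sqrt(power * (1 - power) / it),
                 n_rejections = n_rej, n_total = n1 + n2, spec = spec),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf(
    "Monte-Carlo power: %.3f (MC SE %.4f) at n = %d natural / %d ART,\n",
    x$power, x$mc_se, x$spec$n_natural, x$spec$n_art))
  cat(sprintf("  delta = %g, sigma = %g, t df = %g, alpha = %g, %d iterations\n",
              x$spec$delta, x$spec$sigma, x$spec$df, x$spec$alpha,
              x$spec$n_iter))
  invisible(x)
}

#' Closed-form large-sample power approximation
#'
#' Normal-approximation oracle for [simulate_power()]:
#' `Phi(|delta| / SE - z_{1 - alpha/2})` with
#' `SE = sigma * sqrt(df / (df - 2)) * sqrt(1/n1 + 1/n2)`.
#'
#' @param spec a [power_spec()].
#' @return approximate power in (0, 1).
#' @export
analytic_power <- function(spec) {
  stopifnot(inherits(spec, "power_spec"))
  sd_noise <- spec$sigma * sqrt(spec$df / (spec$df - 2))
  se <- sd_noise * sqrt(1 / spec$n_natural + 1 / spec$n_art)
  stats::pnorm(abs(spec$delta) / se - stats::qnorm(1 - spec$alpha / 2))
}

#' Smallest sample-size multiplier reaching a target power
#'
#' Searches a multiplier grid (step `step`, from 1 up to `cap`) for the
#' smallest k such that [simulate_power()] at group sizes
#' `(ceiling(k * base_n_natural), ceiling(k * base_n_art))` reaches
#' `target_power`. Every evaluation reuses the same seed (common random
#' numbers), which makes estimated power monotone enough in n for bisection
#' over the grid.
#'
#' @param base_n_natural,base_n_art base group sizes.
#' @param target_power target power in (alpha, 1).
#' @param spec a [power_spec()] supplying the model parameters, iteration
#'   count and seed (its group sizes are ignored).
#' @param step multiplier grid step (default 0.1).
#' @param cap largest multiplier considered (default 100).
#' @return list: `multiplier`, the achieved [simulate_power()] result at the
#'   selected sizes, and `n_natural`, `n_art` at that multiplier.
#' @export
required_multiplier <- function(base_n_natural, base_n_art,
                                target_power = 0.80, spec = power_spec(),
                                step = 0.1, cap = 100) {
  stopifnot(target_power > spec$alpha, target_power < 1,
            base_n_natural >= 2L, base_n_art >= 2L)
  grid <- seq(1, cap, by = step)
  eval_at <- function(k) {
    s <- spec
    s$n_natural <- as.integer(ceiling(k * base_n_natural))
    s$n_art <- as.integer(ceiling(k * base_n_art))
    simulate_power(s)
  }
  lo <- 1L
  res_lo <- eval_at(grid[lo])
  if (res_lo$power >= target_power) {
    return(list(multiplier = grid[lo], result = res_lo,
                n_natural = res_lo$spec$n_natural,
                n_art = res_lo$spec$n_art))
  }
  # bracket by doubling before bisecting, so the cap is only ever evaluated
  # when the target is genuinely out of reach
  hi <- lo
  res_hi <- res_lo
  repeat {
    hi <- min(2L * hi, length(grid))
    res_hi <- eval_at(grid[hi])
    if (res_hi$power >= target_power) break
    if (hi == length(grid)) {
      stop("target power ", target_power,
           " not reachable below multiplier cap ", cap)
    }
    lo <- hi
  }
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    res_mid <- eval_at(grid[mid])
    if (res_mid$power >= target_power) {
      hi <- mid
      res_hi <- res_mid
    } else {
      lo <- mid
    }
  }
  list(multiplier = grid[hi], result = res_hi,
       n_natural = res_hi$spec$n_natural, n_art = res_hi$spec$n_art)
}
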