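# Benchmark-dose modeling: least-squares fits over a model family, AIC
# selection, lack-of-fit screening, BMD estimation at BMR = bmrf * sigma
# and profile-likelihood confidence bounds.
#
# Mean-function parameterizations (d = dose):
#   linear            a + b*d
#   poly2             a + b*d + c*d^2
#   power             a + b*d^g,                       g in [0.5, 8]
#   hill              a + (b-a)*d^n/(k^n + d^n),       n in [0.5, 8]
#   log_logistic      a + (b-a)*d^n/(k^n + d^n),       n in (0, 20]
#   weibull           a + (b-a)*(1 - exp(-(d/k)^g)),   g in (0, 8]
#   michaelis_menten  a + (b-a)*d/(k + d)              (hill with n = 1)
#   exponential       a + b*(exp(c*d) - 1)

#' Benchmark-dose configuration
#'
#' @param bmrf benchmark response factor: the BMR is `bmrf` residual
#'   standard deviations (default 1.349, i.e. roughly a 10\% change
#'   relative to controls under constant variance).
#' @param lof_threshold lack-of-fit p-value below which a feature is
#'   discarded (default 0.10, strict `<`).
#' @param ratio_bmd_bmdl,ratio_bmdu_bmd,ratio_bmdu_bmdl maximum allowed
#'   ratios between the estimated doses (defaults 20, 20, 40).
#' @param conf_level two-sided confidence level of the profile-likelihood
#'   BMDL/BMDU bounds (default 0.95).
#' @param dose_cap_factor BMD search cap as a multiple of the highest dose
#'   (default 10).
#' @return list of class `bmd_config`.
#' @export
bmd_config <- function(bmrf = 1.349, lof_threshold = 0.10,
                       ratio_bmd_bmdl = 20, ratio_bmdu_bmd = 20,
                       ratio_bmdu_bmdl = 40, conf_level = 0.95,
                       dose_cap_factor = 10) {
  structure(list(bmrf = bmrf, lof_threshold = lof_threshold,
                 ratio_bmd_bmdl = ratio_bmd_bmdl,
                 ratio_bmdu_bmd = ratio_bmdu_bmd,
                 ratio_bmdu_bmdl = ratio_bmdu_bmdl,
                 conf_level = conf_level,
                 dose_cap_factor = dose_cap_factor),
            class = "bmd_config")
}

# --- model registry -------------------------------------------------------

# each model: fn(d, p); npar; starts(d, y) -> list of start vectors;
# lower/upper bounds on p; amp: index of the amplitude parameter solvable
# in closed form given the BMD; solve_amp(bmd, delta, rest) -> amplitude.

bmd_models <- function() {
  list(
    linear = list(
      npar = 2,
      fn = function(d, p) p[1] + p[2] * d,
      rest_idx = 1, amp_idx = 2,
      solve_amp = function(bmd, delta, rest) delta / bmd),
    poly2 = list(
      npar = 3,
      fn = function(d, p) p[1] + p[2] * d + p[3] * d^2,
      rest_idx = c(1, 3), amp_idx = 2,
      solve_amp = function(bmd, delta, rest) (delta - rest[2] * bmd^2) / bmd),
    power = list(
      npar = 3,  # a, b, g
      fn = function(d, p) p[1] + p[2] * d^p[3],
      rest_idx = c(1, 3), amp_idx = 2,
      lower = c(-Inf, -Inf, 0.5), upper = c(Inf, Inf, 8),
      solve_amp = function(bmd, delta, rest) delta / bmd^rest[2]),
    hill = list(
      npar = 4,  # a, b, k, n
      fn = function(d, p) p[1] + (p[2] - p[1]) * d^p[4] / (p[3]^p[4] + d^p[4]),
      rest_idx = c(1, 3, 4), amp_idx = 2,
      lower = c(-Inf, -Inf, 1e-8, 0.5), upper = c(Inf, Inf, Inf, 8),
      solve_amp = function(bmd, delta, rest) {
        rest[1] + delta * (rest[2]^rest[3] + bmd^rest[3]) / bmd^rest[3]
      }),
    log_logistic = list(
      npar = 4,  # a, b, k, n
      fn = function(d, p) p[1] + (p[2] - p[1]) * d^p[4] / (p[3]^p[4] + d^p[4]),
      rest_idx = c(1, 3, 4), amp_idx = 2,
      lower = c(-Inf, -Inf, 1e-8, 1e-3), upper = c(Inf, Inf, Inf, 20),
      solve_amp = function(bmd, delta, rest) {
        rest[1] + delta * (rest[2]^rest[3] + bmd^rest[3]) / bmd^rest[3]
      }),
    weibull = list(
      npar = 4,  # a, b, k, g
      fn = function(d, p) p[1] + (p[2] - p[1]) * (1 - exp(-(d / p[3])^p[4])),
      rest_idx = c(1, 3, 4), amp_idx = 2,
      lower = c(-Inf, -Inf, 1e-8, 1e-3), upper = c(Inf, Inf, Inf, 8),
      solve_amp = function(bmd, delta, rest) {
        rest[1] + delta / (1 - exp(-(bmd / rest[2])^rest[3]))
      }),
    michaelis_menten = list(
      npar = 3,  # a, b, k
      fn = function(d, p) p[1] + (p[2] - p[1]) * d / (p[3] + d),
      rest_idx = c(1, 3), amp_idx = 2,
      lower = c(-Inf, -Inf, 1e-8), upper = c(Inf, Inf, Inf),
      solve_amp = function(bmd, delta, rest) {
        rest[1] + delta * (rest[2] + bmd) / bmd
      }),
    exponential = list(
      npar = 3,  # a, b, c
      fn = function(d, p) p[1] + p[2] * (exp(p[3] * d) - 1),
      rest_idx = c(1, 3), amp_idx = 2,
      lower = c(-Inf, -Inf, -Inf), upper = c(Inf, Inf, Inf),
      solve_amp = function(bmd, delta, rest) {
        denom <- exp(rest[2] * bmd) - 1
        if (abs(denom) < 1e-12) return(NA_real_)
        delta / denom
      })
  )
}

#' Model families for dose-response fitting
#'
#' `"transcriptomics"` comprises linear, second-order polynomial, hill,
#' power and exponential models; `"qpcr"` extends it with log-logistic,
#' Weibull and Michaelis-Menten.
#'
#' @param family `"transcriptomics"` or `"qpcr"`, or a character vector of
#'   model names.
#' @return character vector of model names.
#' @export
bmd_family <- function(family = c("transcriptomics", "qpcr")) {
  if (length(family) == 1 && family %in% names(bmd_models())) return(family)
  family <- match.arg(family)
  base <- c("linear", "poly2", "hill", "power", "exponential")
  if (family == "qpcr") {
    c(base, "log_logistic", "weibull", "michaelis_menten")
  } else base
}

model_starts <- function(name, d, y) {
  a0 <- mean(y[d == min(d)])
  b0 <- mean(y[d == max(d)])
  dr <- max(d[d > 0])
  span <- b0 - a0
  slope <- if (dr > 0) span / dr else 0
  switch(name,
    linear = list(c(a0, slope)),
    poly2 = list(c(a0, slope, 0)),
    power = lapply(c(0.6, 1, 1.5, 2, 4), function(g)
      c(a0, if (dr > 0) span / dr^g else 0, g)),
    hill = lapply(list(c(0.25, 1), c(0.5, 1), c(0.5, 2), c(1, 2), c(0.25, 4)),
                  function(s) c(a0, b0, s[1] * dr, s[2])),
    log_logistic = lapply(list(c(0.25, 1), c(0.5, 1), c(0.5, 3),
                               c(1, 2), c(0.25, 6)),
                          function(s) c(a0, b0, s[1] * dr, s[2])),
    weibull = lapply(list(c(0.25, 1), c(0.5, 1), c(0.5, 2), c(1, 2),
                          c(0.25, 4)),
                     function(s) c(a0, b0, s[1] * dr, s[2])),
    michaelis_menten = lapply(c(0.1, 0.25, 0.5, 1, 2), function(f)
      c(a0, b0, f * dr)),
    exponential = lapply(c(-2, -0.5, 0.5, 1, 2) / dr, function(cc)
      c(a0, if (abs(cc) > 0) span / (exp(cc * dr) - 1) else slope, cc))
  )
}

fit_one_model <- function(name, d, y) {
  mods <- bmd_models()
  mod <- mods[[name]]
  n <- length(y)
  k <- mod$npar
  par <- NULL
  rss <- Inf
  if (name %in% c("linear", "poly2")) {
    X <- if (name == "linear") cbind(1, d) else cbind(1, d, d^2)
    fit <- stats::lm.fit(X, y)
    par <- unname(fit$coefficients)
    par[is.na(par)] <- 0
    rss <- sum(fit$residuals^2)
  } else {
    df <- data.frame(d = d, y = y)
    lower <- if (is.null(mod$lower)) rep(-Inf, k) else mod$lower
    upper <- if (is.null(mod$upper)) rep(Inf, k) else mod$upper
    for (start in model_starts(name, d, y)) {
      start <- pmin(pmax(start, lower + 1e-9), upper - 1e-9)
      names(start) <- paste0("p", seq_len(k))
      form <- switch(name,
        power = y ~ p1 + p2 * d^p3,
        hill = ,
        log_logistic = y ~ p1 + (p2 - p1) * d^p4 / (p3^p4 + d^p4),
        weibull = y ~ p1 + (p2 - p1) * (1 - exp(-(d / p3)^p4)),
        michaelis_menten = y ~ p1 + (p2 - p1) * d / (p3 + d),
        exponential = y ~ p1 + p2 * (exp(p3 * d) - 1))
      fit <- tryCatch(
        suppressWarnings(minpack.lm::nlsLM(
          form, data = df, start = as.list(start),
          lower = lower, upper = upper,
          control = minpack.lm::nls.lm.control(maxiter = 200))),
        error = function(e) NULL)
      if (!is.null(fit)) {
        r <- sum(stats::resid(fit)^2)
        if (r < rss) {
          rss <- r
          par <- unname(stats::coef(fit))
        }
      }
    }
    if (is.null(par)) return(NULL)
  }
  sigma <- if (n > k) sqrt(rss / (n - k)) else NA_real_
  # common AIC scale across lm and nls paths: n*log(RSS/n) + 2*(k+1);
  # RSS floored at numerical precision relative to the data scale so that
  # exact fits compare by parameter count rather than rounding noise
  rss_floor <- n * (1e-8 * (max(abs(y)) + 1e-12))^2
  aic <- n * log(max(rss, rss_floor) / n) + 2 * (k + 1)
  lof <- lack_of_fit_p(d, y, rss, k)
  list(model = name, par = par, rss = rss, sigma = sigma, aic = aic,
       lof_p = lof, n = n, k = k,
       fn = function(x) mod$fn(x, par))
}

lack_of_fit_p <- function(d, y, rss, k) {
  means <- tapply(y, d, mean)
  sspe <- sum((y - means[as.character(d)])^2)
  n_dose <- length(means)
  df_pe <- length(y) - n_dose
  df_lof <- n_dose - k
  if (df_pe <= 0 || df_lof <= 0) return(NA_real_)
  ss_lof <- max(rss - sspe, 0)
  f_stat <- (ss_lof / df_lof) / (sspe / df_pe)
  stats::pf(f_stat, df_lof, df_pe, lower.tail = FALSE)
}

#' Fit a dose-response model family to one feature
#'
#' Least-squares fits of every model in the family (linear and polynomial
#' by ordinary least squares, the rest by bounded Levenberg-Marquardt with
#' five deterministic starts derived from the data).  Models that fail to
#' converge are excluded with a message.  AIC is computed on a common
#' scale, `n*log(RSS/n) + 2*(k+1)`, valid for comparing fits to the same
#' data.
#'
#' @param dose,response numeric vectors of equal length; at least three
#'   distinct doses including zero.
#' @param family see [bmd_family()].
#' @return list of per-model fit records (model, par, rss, sigma, aic,
#'   lof_p, fn), sorted by AIC ascending.
#' @export
fit_models <- function(dose, response, family = "transcriptomics") {
  stopifnot(length(dose) == length(response))
  if (length(unique(dose)) < 3 || !any(dose == 0)) {
    stop("need at least 3 distinct doses including 0", call. = FALSE)
  }
  fams <- if (length(family) == 1 && family %in%
              c("transcriptomics", "qpcr")) bmd_family(family) else family
  fits <- list()
  for (name in fams) {
    f <- fit_one_model(name, dose, response)
    if (is.null(f)) {
      message("model ", name, " failed to converge; excluded")
    } else {
      fits[[name]] <- f
    }
  }
  fits[order(vapply(fits, `[[`, 0.0, "aic"))]
}

find_bmd <- function(fn, bmr, max_dose, cap_factor = 10) {
  f0 <- fn(0)
  cap <- cap_factor * max_dose
  g <- function(d) abs(fn(d) - f0) - bmr
  grid <- seq(0, cap, length.out = 2000)[-1]
  vals <- vapply(grid, g, 0.0)
  cross <- which(vals >= 0)
  if (length(cross) == 0) return(NA_real_)
  i <- cross[1]
  lo <- if (i == 1) 1e-12 * max_dose else grid[i - 1]
  if (g(lo) >= 0) return(grid[i])
  stats::uniroot(g, c(lo, grid[i]), tol = 1e-12 * max_dose)$root
}

profile_rss <- function(model, d, y, bmd, delta, rest_start) {
  mod <- bmd_models()[[model]]
  bmr <- abs(delta)
  # the candidate dose must be the FIRST crossing of +-BMR, otherwise the
  # parameter vector describes a curve whose BMD is elsewhere (non-monotone
  # models could satisfy the point constraint while crossing earlier)
  pre_grid <- if (bmd > 0) seq(0, bmd, length.out = 40)[-c(1, 40)] else numeric(0)
  obj <- function(rest) {
    amp <- mod$solve_amp(bmd, delta, rest)
    if (!is.finite(amp)) return(1e30)
    p <- numeric(mod$npar)
    p[mod$rest_idx] <- rest
    p[mod$amp_idx] <- amp
    if (!is.null(mod$lower) &&
        (any(p < mod$lower - 1e-12) || any(p > mod$upper + 1e-12))) {
      return(1e30)
    }
    f0 <- mod$fn(0, p)
    excess <- abs(mod$fn(pre_grid, p) - f0) - bmr
    if (any(excess > 1e-9 * bmr)) return(1e30)
    r <- sum((y - mod$fn(d, p))^2)
    if (!is.finite(r)) 1e30 else r
  }
  if (length(rest_start) == 1) {
    opt <- stats::optim(rest_start, obj, method = "Brent",
                        lower = rest_start - 10 * abs(rest_start) - 10,
                        upper = rest_start + 10 * abs(rest_start) + 10)
  } else {
    opt <- stats::optim(rest_start, obj, method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-10))
  }
  opt$value
}

#' Estimate BMD, BMDL and BMDU from a fitted model
#'
#' The benchmark response is `BMR = bmrf * sigma`, with `sigma` the
#' residual standard deviation of the fit (constant-variance assumption).
#' The BMD is the smallest positive dose at which the fitted curve departs
#' from its value at dose zero by BMR in either direction, searched up to
#' `dose_cap_factor` times the highest dose.  BMDL and BMDU are two-sided
#' profile-likelihood bounds: the deviance statistic
#' `n * log(RSS(bmd) / RSS_hat)` is compared against the chi-square
#' quantile at `conf_level` with one degree of freedom, re-optimizing all
#' remaining parameters at each candidate BMD.
#'
#' @param fit one fit record from [fit_models()].
#' @param dose,response the data the model was fitted to.
#' @param config a [bmd_config()].
#' @param bounds compute BMDL/BMDU (default `TRUE`); skipping them saves
#'   the profile-likelihood optimization when only the point estimate is
#'   needed.
#' @return list with `bmd`, `bmdl`, `bmdu` (each `NA` when not
#'   estimable) and `bmr`.
#' @export
estimate_bmd <- function(fit, dose, response, config = bmd_config(),
                         bounds = TRUE) {
  scale_y <- max(abs(response)) + 1e-300
  if (!is.finite(fit$sigma) || fit$sigma <= 1e-9 * scale_y) {
    # residual SD at numerical zero: the BMR is degenerate (flat or
    # exact fit)
    return(list(bmd = NA_real_, bmdl = NA_real_, bmdu = NA_real_,
                bmr = NA_real_))
  }
  bmr <- config$bmrf * fit$sigma
  max_dose <- max(dose)
  bmd <- find_bmd(fit$fn, bmr, max_dose, config$dose_cap_factor)
  if (!is.finite(bmd) || bmd <= 0) {
    return(list(bmd = NA_real_, bmdl = NA_real_, bmdu = NA_real_, bmr = bmr))
  }
  if (!bounds) {
    return(list(bmd = bmd, bmdl = NA_real_, bmdu = NA_real_, bmr = bmr))
  }
  mod <- bmd_models()[[fit$model]]
  sign_delta <- sign(fit$fn(bmd) - fit$fn(0))
  if (sign_delta == 0) sign_delta <- 1
  delta <- sign_delta * bmr
  rest_start <- fit$par[mod$rest_idx]
  crit <- stats::qchisq(config$conf_level, df = 1)
  n <- fit$n
  rss_hat <- max(fit$rss, 1e-300)
  stat <- function(b) {
    rssb <- profile_rss(fit$model, dose, response, b, delta, rest_start)
    n * log(max(rssb, 1e-300) / rss_hat) - crit
  }
  bmdl <- tryCatch({
    lo <- bmd * 1e-4
    if (stat(lo) <= 0) NA_real_ else
      stats::uniroot(stat, c(lo, bmd), tol = bmd * 1e-6)$root
  }, error = function(e) NA_real_)
  bmdu <- tryCatch({
    hi <- config$dose_cap_factor * max_dose
    if (stat(hi) <= 0) NA_real_ else
      stats::uniroot(stat, c(bmd, hi), tol = bmd * 1e-6)$root
  }, error = function(e) NA_real_)
  list(bmd = bmd, bmdl = bmdl, bmdu = bmdu, bmr = bmr)
}

#' Apply the pass/fail filters to per-feature optimal fits
#'
#' A feature fails with reason `"lack_of_fit"` when the optimal model's
#' lack-of-fit p-value is below the threshold (strict `<` 0.10 by
#' default), `"no_bmd"` when any of BMD/BMDL/BMDU is missing,
#' `"max_dose"` when BMD or BMDU exceeds the highest tested dose, and
#' `"ratio"` when BMD/BMDL, BMDU/BMD or BMDU/BMDL exceed their limits
#' (20, 20 and 40 by default).  Features passing all filters are flagged
#' as dose-dependently altered.
#'
#' @param results data.frame with columns `feature`, `lof_p`, `bmd`,
#'   `bmdl`, `bmdu`.
#' @param max_dose highest tested dose.
#' @param config a [bmd_config()].
#' @return the input with added logical `pass` and character `reason`
#'   columns (`""` for passing features).
#' @export
bmd_filter <- function(results, max_dose, config = bmd_config()) {
  reason <- character(nrow(results))
  for (i in seq_len(nrow(results))) {
    r <- results[i, ]
    if (is.finite(r$lof_p) && r$lof_p < config$lof_threshold) {
      reason[i] <- "lack_of_fit"
    } else if (!is.finite(r$bmd) || !is.finite(r$bmdl) || !is.finite(r$bmdu)) {
      reason[i] <- "no_bmd"
    } else if (r$bmd > max_dose || r$bmdu > max_dose) {
      reason[i] <- "max_dose"
    } else if (r$bmd / r$bmdl > config$ratio_bmd_bmdl ||
               r$bmdu / r$bmd > config$ratio_bmdu_bmd ||
               r$bmdu / r$bmdl > config$ratio_bmdu_bmdl) {
      reason[i] <- "ratio"
    }
  }
  results$pass <- reason == ""
  results$reason <- reason
  results
}

#' Full benchmark-dose analysis of a long-format expression table
#'
#' For every feature: fit the model family, select the lowest-AIC model,
#' estimate BMD/BMDL/BMDU and apply the filters.
#'
#' @param data data.frame with columns `feature`, `dose`, `response`.
#' @param family see [bmd_family()].
#' @param config a [bmd_config()].
#' @param max_dose highest tested dose (default: max of `data$dose`).
#' @return data.frame with one row per feature: `feature`, `model`,
#'   `aic`, `lof_p`, `bmd`, `bmdl`, `bmdu`, `pass`, `reason`.
#' @export
bmd_analysis <- function(data, family = "transcriptomics",
                         config = bmd_config(),
                         max_dose = max(data$dose)) {
  rows <- lapply(split(data, data$feature), function(block) {
    fits <- fit_models(block$dose, block$response, family)
    if (length(fits) == 0) {
      return(data.frame(feature = block$feature[1], model = NA_character_,
                        aic = NA_real_, lof_p = NA_real_, bmd = NA_real_,
                        bmdl = NA_real_, bmdu = NA_real_,
                        stringsAsFactors = FALSE))
    }
    best <- fits[[1]]
    est <- estimate_bmd(best, block$dose, block$response, config)
    data.frame(feature = block$feature[1], model = best$model,
               aic = best$aic, lof_p = best$lof_p, bmd = est$bmd,
               bmdl = est$bmdl, bmdu = est$bmdu, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  bmd_filter(out, max_dose, config)
}
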