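# Moments of a winsorized (range-clamped) normal / lognormal variable.
# Used to calibrate the generator so that the *clamped* draws, not the
# underlying family, hit the target mean/sd.
wins_norm_moments <- function(m, s, lo, hi) {
  a <- (lo - m) / s
  b <- (hi - m) / s
  Pa <- stats::pnorm(a); Pb <- stats::pnorm(b)
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  M1 <- lo * Pa + hi * (1 - Pb) + m * (Pb - Pa) + s * (da - db)
  Emid2 <- m^2 * (Pb - Pa) + 2 * m * s * (da - db) +
    s^2 * ((Pb - Pa) + a * da - b * db)
  M2 <- lo^2 * Pa + hi^2 * (1 - Pb) + Emid2
  c(mean = M1, sd = sqrt(max(M2 - M1^2, 0)))
}

wins_lnorm_moments <- function(mu, sig, lo, hi) {
  z <- function(t, k) if (t <= 0) -Inf else (log(t) - mu - k * sig^2) / sig
  Plo <- if (lo <= 0) 0 else stats::plnorm(lo, mu, sig)
  Phi <- stats::plnorm(hi, mu, sig)
  E1 <- exp(mu + sig^2 / 2) * (stats::pnorm(z(hi, 1)) - stats::pnorm(z(lo, 1)))
  E2 <- exp(2 * mu + 2 * sig^2) *
    (stats::pnorm(z(hi, 2)) - stats::pnorm(z(lo, 2)))
  M1 <- lo * Plo + hi * (1 - Phi) + E1
  M2 <- lo^2 * Plo + hi^2 * (1 - Phi) + E2
  c(mean = M1, sd = sqrt(max(M2 - M1^2, 0)))
}

# Solve for the underlying (location, scale) whose winsorized moments
# match the targets. Relative squared-error objective, Nelder-Mead.
match_winsorized_moments <- function(family, target_mean, target_sd, lo, hi) {
  momfun <- switch(family, normal = wins_norm_moments,
                   lognormal = wins_lnorm_moments,
                   stop("unknown family: ", family))
  start <- if (family == "normal") {
    c(target_mean, log(target_sd))
  } else {
    cv2 <- (target_sd / target_mean)^2
    s2 <- log(1 + cv2)
    c(log(target_mean) - s2 / 2, log(sqrt(s2)))
  }
  obj <- function(p) {
    mo <- momfun(p[1], exp(p[2]), lo, hi)
    (mo[1] / target_mean - 1)^2 + (mo[2] / target_sd - 1)^2
  }
  o <- stats::optim(start, obj, control = list(maxit = 5000, reltol = 1e-14))
  if (o$value > 1e-8) {
    stop("could not match winsorized moments for family ", family)
  }
  c(location = o$par[1], scale = exp(o$par[2]))
}

#' Configuration of the synthetic monitoring-site generator
#'
#' Defines the marginal distribution of each indicator, the
#' upstream-to-downstream degradation gradient, the detection limits
#' and the stratum sizes that [generate_sites()] draws from. The
#' defaults emulate the descriptive statistics of the 83-site reservoir
#' survey the package's evaluation method targets: DO and CODMn are
#' (range-clamped) normal, TN, NH3N and TP are right-skewed lognormal,
#' each clamped to the observed min-max range and calibrated so that
#' the clamped draws reproduce the published mean and standard
#' deviation (TN: mean 2.277, sd 3.714, max 18.94 mg/L, a heavy right
#' tail). Stratum sizes default to 18 main-stream and 65 tributary
#' sites (23/23/19 across upstream/midstream/downstream).
#'
#' @param n_sites Data frame with columns `reach`, `section`, `n`;
#'   defaults to the 83-site layout above.
#' @param gradient List with `cost_factor` (multiplicative degradation
#'   of cost indicators: upstream x(1-f), midstream x1, downstream
#'   x(1+f); default 0.25) and `do_shift` (additive DO depression in
#'   mg/L: +shift upstream, -shift downstream; default 1.0).
#' @param lod Named detection limits; draws below them are stored as
#'   0.0 (default TN 0.05, TP 0.005 mg/L).
#' @param rho Gaussian-copula correlation shared by TN, NH3N and TP
#'   (default 0 = independent indicators).
#' @return Object of class `synthetic_config`.
#' @export
#' @examples
#' cfg <- synthetic_config()
#' cfg$marginals$TN
synthetic_config <- function(n_sites = NULL,
                             gradient = list(cost_factor = 0.25,
                                             do_shift = 1.0),
                             lod = c(TN = 0.05, TP = 0.005),
                             rho = 0) {
  if (is.null(n_sites)) {
    n_sites <- data.frame(
      reach = c(rep("main", 3), rep("tributary", 3)),
      section = rep(c("upstream", "midstream", "downstream"), 2),
      n = c(6, 6, 6, 23, 23, 19),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(all(c("reach", "section", "n") %in% names(n_sites)),
            all(n_sites$n >= 0), rho >= 0, rho < 1)
  targets <- list(
    DO    = list(family = "normal",    mean = 9.219, sd = 2.567,
                 lo = 4.89, hi = 18.36),
    TN    = list(family = "lognormal", mean = 2.277, sd = 3.714,
                 lo = 0,    hi = 18.94),
    NH3N  = list(family = "lognormal", mean = 0.271, sd = 0.374,
                 lo = 0.02, hi = 2.74),
    TP    = list(family = "lognormal", mean = 0.031, sd = 0.039,
                 lo = 0,    hi = 0.30),
    CODMn = list(family = "normal",    mean = 1.942, sd = 1.236,
                 lo = 0,    hi = 4.84)
  )
  marginals <- lapply(targets, function(t) {
    if (t$sd <= 0) stop("marginal sd must be positive")
    par <- match_winsorized_moments(t$family, t$mean, t$sd, t$lo, t$hi)
    c(t, list(location = unname(par[1]), scale = unname(par[2])))
  })
  structure(
    list(n_sites = n_sites, marginals = marginals, gradient = gradient,
         lod = lod, rho = rho),
    class = "synthetic_config"
  )
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("Synthetic site generator:", sum(x$n_sites$n), "sites (",
      sum(x$n_sites$n[x$n_sites$reach == "main"]), "main,",
      sum(x$n_sites$n[x$n_sites$reach == "tributary"]), "tributary )\n")
  for (ind in names(x$marginals)) {
    m <- x$marginals[[ind]]
    cat(sprintf("  %-5s %-9s target mean %.3f sd %.3f, range [%g, %g]\n",
                ind, m$family, m$mean, m$sd, m$lo, m$hi))
  }
  invisible(x)
}

# section multipliers / shifts used by the gradient
.section_level <- c(upstream = -1, midstream = 0, downstream = 1, none = 0)

#' Generate synthetic monitoring sites
#'
#' Draws a reproducible site table from a [synthetic_config()]:
#' indicator values come from the calibrated marginals (via a Gaussian
#' copula when `rho > 0`), degrade stochastically from upstream to
#' downstream, are clamped to the configured ranges and left-censored
#' to 0 below the detection limits.
#'
#' @param config A `synthetic_config`.
#' @param seed Integer seed; the same seed always reproduces the same
#'   table.
#' @return Data frame of site records (columns `site_id`, `reach`,
#'   `section`, `DO`, `TN`, `NH3N`, `TP`, `CODMn`), ready for
#'   [validate_samples()] or [fce()].
#' @export
#' @examples
#' sites <- generate_sites(seed = 42)
#' nrow(sites)
generate_sites <- function(config = synthetic_config(), seed) {
  stopifnot(inherits(config, "synthetic_config"))
  if (missing(seed)) stop("a seed is required for reproducibility")
  set.seed(seed)
  inds <- wq_indicators()
  corr_set <- c("TN", "NH3N", "TP")
  g <- config$gradient
  strata <- config$n_sites
  counters <- c(main = 0L, tributary = 0L)
  prefix <- c(main = "WA", tributary = "L")
  out <- vector("list", nrow(strata))
  for (r in seq_len(nrow(strata))) {
    n <- strata$n[r]
    if (n == 0) next
    reach <- strata$reach[r]
    section <- strata$section[r]
    lev <- .section_level[[section]]
    # latent normals; TN/NH3N/TP share a common factor when rho > 0
    z <- matrix(stats::rnorm(n * 5), n, 5, dimnames = list(NULL, inds))
    if (config$rho > 0) {
      z0 <- stats::rnorm(n)
      for (ind in corr_set) {
        z[, ind] <- sqrt(config$rho) * z0 + sqrt(1 - config$rho) * z[, ind]
      }
    }
    vals <- sapply(inds, function(ind) {
      m <- config$marginals[[ind]]
      x <- if (m$family == "normal") {
        m$location + m$scale * z[, ind]
      } else {
        exp(m$location + m$scale * z[, ind])
      }
      if (ind == "DO") {
        x <- x - lev * g$do_shift
      } else {
        x <- x * (1 + lev * g$cost_factor)
      }
      x <- pmin(pmax(x, m$lo), m$hi)
      if (ind %in% names(config$lod)) {
        x[x < config$lod[[ind]]] <- 0
      }
      x
    })
    vals <- matrix(vals, nrow = n, dimnames = list(NULL, inds))
    ids <- paste0(prefix[[reach]], counters[[reach]] + seq_len(n))
    counters[[reach]] <- counters[[reach]] + n
    out[[r]] <- cbind(
      data.frame(site_id = ids, reach = reach, section = section,
                 stringsAsFactors = FALSE),
      as.data.frame(vals)
    )
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Generate a planted-grade cohort
#'
#' Draws sites whose true quality class is known by construction: each
#' site is assigned a planted grade and all five of its concentrations
#' are drawn uniformly from the central `central` fraction of that
#' grade's interval in the scheme, making the grades nearly separable.
#' Used for recovery testing of the evaluation chain. The unbounded DO
#' grade-I interval is given a synthetic upper edge one grade-II width
#' above its regulatory bound.
#'
#' @param n Number of sites.
#' @param grade_mix Probabilities of grades I-V (sums to 1).
#' @param seed Integer seed.
#' @param scheme Scheme id or `grade_scheme`.
#' @param central Fraction of each interval to draw from (default 0.6).
#' @return List of class `planted_cohort`: `samples` (site data frame)
#'   and `planted` (integer grades, recorded before any evaluation).
#' @export
#' @examples
#' coh <- generate_planted_cohort(20, seed = 7)
#' table(coh$planted)
generate_planted_cohort <- function(n, grade_mix = rep(0.2, 5), seed,
                                    scheme = "customized", central = 0.6) {
  if (missing(seed)) stop("a seed is required for reproducibility")
  if (length(grade_mix) != 5 || any(grade_mix < 0) || sum(grade_mix) == 0) {
    stop("grade_mix must be 5 non-negative values with positive sum")
  }
  grade_mix <- grade_mix / sum(grade_mix)
  if (is.character(scheme)) scheme <- load_scheme(scheme)
  set.seed(seed)
  planted <- sample.int(5, n, replace = TRUE, prob = grade_mix)
  inds <- wq_indicators()
  b <- scheme$bounds
  vals <- sapply(inds, function(ind) {
    bi <- b[b$indicator == ind, ]
    bi <- bi[order(bi$grade), ]
    lower <- bi$lower
    upper <- bi$upper
    if (!is.finite(upper[1])) {
      # DO grade I: synthetic edge one grade-II width above the bound
      upper[1] <- lower[1] + (upper[2] - lower[2])
    }
    mid <- (lower[planted] + upper[planted]) / 2
    half <- (upper[planted] - lower[planted]) * central / 2
    stats::runif(n, mid - half, mid + half)
  })
  vals <- matrix(vals, nrow = n, dimnames = list(NULL, inds))
  samples <- cbind(
    data.frame(site_id = sprintf("P%d", seq_len(n)), reach = "main",
               section = "none", stringsAsFactors = FALSE),
    as.data.frame(vals)
  )
  structure(list(samples = samples, planted = planted),
            class = "planted_cohort")
}

#' Generate an emission inventory
#'
#' Without a seed, returns the packaged reservoir inventory verbatim
#' (see [wanan_inventory()]). With a seed, returns a randomized
#' inventory with the same source/subcategory/pollutant structure and
#' not-assessed pattern, with assessed amounts jittered lognormally
#' around the packaged values — useful for property sweeps of the
#' accounting functions.
#'
#' @param seed Optional integer seed for the randomized variant.
#' @param sdlog Lognormal jitter scale (default 0.5).
#' @return An `emission_ledger` data frame.
#' @export
generate_emission_inventory <- function(seed = NULL, sdlog = 0.5) {
  led <- wanan_inventory()
  if (is.null(seed)) return(led)
  set.seed(seed)
  assessed <- !is.na(led$amount_t_per_a)
  led$amount_t_per_a[assessed] <- stats::rlnorm(
    sum(assessed), meanlog = log(led$amount_t_per_a[assessed]), sdlog = sdlog
  )
  led
}
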