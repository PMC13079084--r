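#' Define an isotopic end member
#'
#' An end member is a named carbon source characterized by the mean and
#' standard deviation of each isotopic tracer: delta 13C (permil VPDB) and
#' F14C (fraction modern). Typical sources for lake DIC are ancient peat
#' soil organic carbon, modern organic carbon (DOC/POC) and atmospheric
#' CO2 corrected for dissolution fractionation.
#'
#' @param name Source label, e.g. `"peat"`, `"modern"`, `"atmosphere"`.
#' @param d13c Length-2 numeric `c(mean, sd)` in permil VPDB.
#' @param f14c Length-2 numeric `c(mean, sd)`, fraction modern.
#' @return An object of class `end_member`.
#' @examples
#' end_member("atmosphere", d13c = c(-9.80, 0.10), f14c = c(1.01, 0.01))
#' @export
end_member <- function(name, d13c, f14c) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.numeric(d13c), length(d13c) == 2L, all(is.finite(d13c)),
            is.numeric(f14c), length(f14c) == 2L, all(is.finite(f14c)))
  if (d13c[2] < 0 || f14c[2] < 0) {
    stop("end member '", name, "': tracer sds must be >= 0", call. = FALSE)
  }
  if (f14c[1] <= 0) {
    stop("end member '", name, "': F14C mean must be > 0", call. = FALSE)
  }
  structure(
    list(name = name,
         d13c_mean = d13c[1], d13c_sd = d13c[2],
         f14c_mean = f14c[1], f14c_sd = f14c[2]),
    class = "end_member"
  )
}

#' Define a mixture observation
#'
#' The measured pool (for lake studies, DIC of a water body) treated as a
#' mixture of end members. Same tracer parameterization as [end_member()].
#'
#' @param label Water-body label.
#' @param d13c,f14c Length-2 numeric `c(mean, sd)` per tracer.
#' @return An object of class `mixture_obs`.
#' @export
mixture_obs <- function(label, d13c, f14c) {
  em <- end_member(label, d13c, f14c)
  names(em)[1] <- "label"
  class(em) <- "mixture_obs"
  em
}

#' Assemble a mixing problem
#'
#' Binds end members, a mixture observation and a conceptual gas-exchange
#' model into one inference problem:
#'
#' * `"equilibration"` - the mixture is a three-way blend of peat, modern
#'   and atmospheric sources, constrained by both delta 13C and F14C
#'   (3 sources, 2 tracers, plus mass balance).
#' * `"outgassing"` - strong CO2 evasion prevents atmospheric
#'   equilibration; the mixture is a two-way blend constrained by F14C
#'   only, because kinetic fractionation during outgassing perturbs
#'   delta 13C while F14C is by definition fractionation-corrected
#'   (2 sources, 1 tracer, plus mass balance).
#'
#' @param model `"equilibration"` or `"outgassing"`.
#' @param sources List of [end_member()] objects, in order. Exactly 3 for
#'   equilibration, exactly 2 for outgassing.
#' @param mixture A [mixture_obs()].
#' @return An object of class `mixing_problem` with a `tracers` field
#'   (`c("d13c", "f14c")` or `"f14c"`).
#' @export
mixing_problem <- function(model = c("equilibration", "outgassing"),
                           sources, mixture) {
  model <- match.arg(model)
  stopifnot(is.list(sources),
            all(vapply(sources, inherits, logical(1), "end_member")),
            inherits(mixture, "mixture_obs"))
  n_src <- length(sources)
  if (model == "equilibration" && n_src != 3L) {
    stop("equilibration model requires exactly 3 sources, got ", n_src,
         call. = FALSE)
  }
  if (model == "outgassing" && n_src != 2L) {
    stop("outgassing model requires exactly 2 sources, got ", n_src,
         call. = FALSE)
  }
  nm <- vapply(sources, `[[`, character(1), "name")
  if (anyDuplicated(nm)) {
    stop("duplicate source names: ", paste(nm[duplicated(nm)], collapse = ", "),
         call. = FALSE)
  }
  tracers <- if (model == "equilibration") c("d13c", "f14c") else "f14c"
  structure(
    list(model = model, sources = sources, mixture = mixture,
         tracers = tracers, source_names = nm),
    class = "mixing_problem"
  )
}

#' @export
print.mixing_problem <- function(x, ...) {
  cat(sprintf("<mixing_problem> model = %s; tracers = %s\n", x$model,
              paste(x$tracers, collapse = ", ")))
  cat("  sources:", paste(x$source_names, collapse = ", "), "\n")
  cat("  mixture:", x$mixture$label, "\n")
  invisible(x)
}

# Elementwise Cramer solutions for the k-source mass-balance system
# [tracer rows; ones row] f = [mixture tracers; 1]. Used both by the
# scalar exact solver and the vectorized Monte Carlo, so the two paths
# are arithmetically identical.
.unmix2 <- function(t1, t2, m) {
  det <- t1 - t2
  cbind((m - t2) / det, (t1 - m) / det)
}

.unmix3 <- function(a1, a2, a3, b1, b2, b3, ma, mb) {
  det <- a1 * (b2 - b3) - a2 * (b1 - b3) + a3 * (b1 - b2)
  f1 <- (ma * (b2 - b3) - a2 * (mb - b3) + a3 * (mb - b2)) / det
  f2 <- (a1 * (mb - b3) - ma * (b1 - b3) + a3 * (b1 - mb)) / det
  f3 <- (a1 * (b2 - mb) - a2 * (b1 - mb) + ma * (b1 - b2)) / det
  cbind(f1, f2, f3)
}

#' Exact linear un-mixing
#'
#' Solves the end-member mixing system for the fractional contribution of
#' each of k sources to a mixture, given k - 1 conservative tracers plus
#' the mass-balance row (fractions sum to 1): `[S; 1'] f = [m; 1]`, where
#' `S[t, j]` is tracer t of source j and `m[t]` the mixture tracer values.
#' The solution is unique when the design matrix is non-singular and is
#' deliberately NOT clamped - fractions outside [0, 1] are returned as-is
#' (the Monte Carlo wrapper, not this solver, applies the feasibility
#' filter).
#'
#' @param sources Either a numeric matrix with one row per tracer and one
#'   column per source (column names used as source names), or a
#'   [mixing_problem()] whose tracer means are used.
#' @param mixture Numeric vector of mixture tracer values, one per tracer
#'   row. Ignored when `sources` is a `mixing_problem`.
#' @return Named numeric vector of fractions summing to 1.
#' @examples
#' # two sources, F14C only: modern 1.0, peat 0.4, mixture 0.76
#' solve_exact(matrix(c(0.4, 1.0), 1, dimnames = list(NULL, c("peat", "modern"))),
#'             0.76)
#' @export
solve_exact <- function(sources, mixture = NULL) {
  if (inherits(sources, "mixing_problem")) {
    pr <- sources
    S <- .tracer_matrix(pr)
    m <- .mixture_vector(pr)
    nm <- pr$source_names
  } else {
    S <- as.matrix(sources)
    m <- mixture
    nm <- colnames(S)
    if (is.null(nm)) nm <- paste0("source", seq_len(ncol(S)))
  }
  k <- ncol(S)
  if (nrow(S) != k - 1L) {
    stop("need k - 1 tracers for k sources: got ", nrow(S), " tracer(s) for ",
         k, " source(s)", call. = FALSE)
  }
  if (length(m) != nrow(S)) {
    stop("mixture supplies ", length(m), " tracer value(s) but k - 1 tracers",
         " are required here (", nrow(S), ")", call. = FALSE)
  }
  A <- rbind(S, rep(1, k))
  if (rcond(A) < 1e-12) {
    stop("singular mixing system: end members {",
         paste(nm, collapse = ", "),
         "} are collinear in tracer space", call. = FALSE)
  }
  f <- if (k == 2L) {
    drop(.unmix2(S[1, 1], S[1, 2], m[1]))
  } else if (k == 3L) {
    drop(.unmix3(S[1, 1], S[1, 2], S[1, 3],
                 S[2, 1], S[2, 2], S[2, 3], m[1], m[2]))
  } else {
    drop(solve(A, c(m, 1)))
  }
  stats::setNames(as.numeric(f), nm)
}

.tracer_matrix <- function(problem, which = "mean") {
  suffix <- paste0("_", which)
  vals <- vapply(problem$sources, function(s) {
    vapply(problem$tracers, function(tr) s[[paste0(tr, suffix)]], numeric(1))
  }, numeric(length(problem$tracers)))
  matrix(vals, nrow = length(problem$tracers),
         dimnames = list(problem$tracers, problem$source_names))
}

.mixture_vector <- function(problem, which = "mean") {
  suffix <- paste0("_", which)
  vapply(problem$tracers, function(tr) problem$mixture[[paste0(tr, suffix)]],
         numeric(1))
}

#' Monte Carlo rejection sampling for a mixing problem
#'
#' Runs `n_iter` simulations. In each iteration every end-member tracer and
#' every mixture tracer is drawn independently from a normal distribution
#' with its stated mean and standard deviation (draws are not truncated;
#' feasibility is enforced only through the rejection step). The linear
#' system is solved exactly for the source fractions, and the draw is
#' retained if and only if all fractions lie in the closed interval
#' \[0, 1\]. Draws yielding a singular system (non-finite fractions) are
#' rejected. Summary statistics are computed over retained draws only.
#'
#' @param problem A [mixing_problem()].
#' @param n_iter Number of simulations (default 100,000).
#' @param seed Integer RNG seed; recorded in the output.
#' @param keep_draws Keep the raw (pre-rejection) fraction draws in the
#'   result (`draws` element) so the rejection step can be audited.
#' @return An object of class `posterior_summary`: `fractions_mean`,
#'   `fractions_sd` (sample s.d.), `n_iter`, `n_accepted`,
#'   `acceptance_rate`, `samples` (accepted fraction vectors, one row per
#'   draw), `seed`, `model`.
#' @export
run_monte_carlo <- function(problem, n_iter = 100000L, seed,
                            keep_draws = FALSE) {
  stopifnot(inherits(problem, "mixing_problem"))
  n_iter <- as.integer(n_iter)
  if (is.na(n_iter) || n_iter < 1L) stop("n_iter must be >= 1", call. = FALSE)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  set.seed(as.integer(seed))

  k <- length(problem$sources)
  # Fixed draw order: each source in order (tracers in problem$tracers
  # order), then the mixture tracers. Determinism depends on this order.
  src_draws <- lapply(problem$sources, function(s) {
    vapply(problem$tracers, function(tr) {
      stats::rnorm(n_iter, s[[paste0(tr, "_mean")]], s[[paste0(tr, "_sd")]])
    }, numeric(n_iter))
  })
  mix_draws <- vapply(problem$tracers, function(tr) {
    stats::rnorm(n_iter, problem$mixture[[paste0(tr, "_mean")]],
                 problem$mixture[[paste0(tr, "_sd")]])
  }, numeric(n_iter))

  fr <- if (k == 2L) {
    .unmix2(src_draws[[1]][, 1], src_draws[[2]][, 1], mix_draws[, 1])
  } else {
    .unmix3(src_draws[[1]][, 1], src_draws[[2]][, 1], src_draws[[3]][, 1],
            src_draws[[1]][, 2], src_draws[[2]][, 2], src_draws[[3]][, 2],
            mix_draws[, 1], mix_draws[, 2])
  }
  colnames(fr) <- problem$source_names

  ok <- rowSums(is.finite(fr) & fr >= 0 & fr <= 1) == k
  n_acc <- sum(ok)
  if (n_acc == 0L) {
    viol_lo <- colMeans(is.finite(fr) & fr < 0)
    viol_hi <- colMeans(is.finite(fr) & fr > 1)
    worst <- which.max(c(viol_lo, viol_hi))
    side <- if (worst > k) "> 1" else "< 0"
    src <- problem$source_names[(worst - 1L) %% k + 1L]
    stop(sprintf(paste0("zero accepted draws (acceptance_rate = 0 over %d ",
                        "iterations); most-violated constraint: fraction ",
                        "'%s' %s in %.1f%% of draws"),
                 n_iter, src, side,
                 100 * max(viol_lo, viol_hi)), call. = FALSE)
  }
  samples <- fr[ok, , drop = FALSE]
  out <- structure(
    list(
      fractions_mean = colMeans(samples),
      fractions_sd = apply(samples, 2, stats::sd),
      n_iter = n_iter,
      n_accepted = n_acc,
      acceptance_rate = n_acc / n_iter,
      samples = samples,
      seed = as.integer(seed),
      model = problem$model
    ),
    class = "posterior_summary"
  )
  if (keep_draws) out$draws <- fr
  out
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("<posterior_summary> model = %s; %d/%d accepted (%.1f%%); seed = %d\n",
              x$model, x$n_accepted, x$n_iter, 100 * x$acceptance_rate, x$seed))
  for (nm in names(x$fractions_mean)) {
    cat(sprintf("  f_%s = %.3f +/- %.3f\n", nm,
                x$fractions_mean[[nm]], x$fractions_sd[[nm]]))
  }
  invisible(x)
}

.extract_ms <- function(x, source, which) {
  if (inherits(x, "posterior_summary")) {
    if (!source %in% names(x$fractions_mean)) {
      stop("source '", source, "' not present in ", which,
           " posterior summary", call. = FALSE)
    }
    list(mean = unname(x$fractions_mean[[source]]),
         sd = unname(x$fractions_sd[[source]]),
         samples = x$samples[, source])
  } else {
    stopifnot(is.list(x), !is.null(x$mean), !is.null(x$sd))
    list(mean = x$mean, sd = x$sd, samples = NULL)
  }
}

#' Inverse-variance weighted combination of two model posteriors
#'
#' Combines the posterior estimates of one source's fractional
#' contribution under two conceptual models into a single estimate, each
#' model weighted by the inverse of its posterior variance (1/s.d.^2):
#' `mean = (m_a w_a + m_b w_b) / (w_a + w_b)` with `w = 1/s^2`.
#'
#' Two uncertainty modes are available. `"analytic"` (default) is standard
#' inverse-variance pooling, `sd = sqrt(1 / (w_a + w_b))`. `"pooled"`
#' computes the s.d. of the inverse-variance-weighted union of the two
#' posterior sample sets about the combined mean (each sample from model x
#' carries weight `w_x / n_x`), which retains non-normal posterior shape;
#' it requires `posterior_summary` inputs.
#'
#' @param a,b `posterior_summary` objects (or bare `list(mean=, sd=)` for
#'   the analytic mode).
#' @param source Name of the source whose fraction is combined (for
#'   summaries); ignored for bare-list inputs.
#' @param sd_mode `"analytic"` or `"pooled"`.
#' @return An object of class `combined_estimate` with `mean`, `sd`,
#'   `weights`, `sd_mode`, `source` and `components`.
#' @export
combine_inverse_variance <- function(a, b, source = "peat",
                                     sd_mode = c("analytic", "pooled")) {
  sd_mode <- match.arg(sd_mode)
  ea <- .extract_ms(a, source, "first")
  eb <- .extract_ms(b, source, "second")
  if (ea$sd <= 0 || eb$sd <= 0) {
    # Degenerate limit: both posteriors exact and in agreement. This is
    # the sds -> 0 limit of inverse-variance weighting and keeps the
    # noise-free recovery path well defined.
    if (ea$sd == 0 && eb$sd == 0 && abs(ea$mean - eb$mean) <= 1e-12) {
      return(structure(
        list(mean = ea$mean, sd = 0, weights = c(a = Inf, b = Inf),
             sd_mode = sd_mode, source = source,
             components = list(a = a, b = b)),
        class = "combined_estimate"
      ))
    }
    stop("posterior s.d. must be > 0 in both models (inverse-variance ",
         "weight undefined)", call. = FALSE)
  }
  wa <- 1 / ea$sd^2
  wb <- 1 / eb$sd^2
  m <- (ea$mean * wa + eb$mean * wb) / (wa + wb)
  s <- if (sd_mode == "analytic") {
    sqrt(1 / (wa + wb))
  } else {
    if (is.null(ea$samples) || is.null(eb$samples)) {
      stop("sd_mode = 'pooled' requires posterior_summary inputs with samples",
           call. = FALSE)
    }
    w <- c(rep(wa / length(ea$samples), length(ea$samples)),
           rep(wb / length(eb$samples), length(eb$samples)))
    x <- c(ea$samples, eb$samples)
    sqrt(sum(w * (x - m)^2) / sum(w))
  }
  structure(
    list(mean = m, sd = s, weights = c(a = wa, b = wb), sd_mode = sd_mode,
         source = source, components = list(a = a, b = b)),
    class = "combined_estimate"
  )
}

#' @export
print.combined_estimate <- function(x, ...) {
  cat(sprintf("<combined_estimate> f_%s = %.3f +/- %.3f (%s s.d.; weights %.1f / %.1f)\n",
              x$source, x$mean, x$sd, x$sd_mode,
              x$weights[["a"]], x$weights[["b"]]))
  invisible(x)
}

#' Check statistical consistency of two model posteriors
#'
#' Two models agree on a source's contribution if their means differ by no
#' more than `k` combined standard deviations:
#' `|m_a - m_b| <= k * sqrt(s_a^2 + s_b^2)`.
#'
#' @inheritParams combine_inverse_variance
#' @param k Multiplier on the combined s.d. (default 1).
#' @return An object of class `consistency_report` with `consistent`
#'   (logical), `delta`, `threshold` and `z` (`delta` in combined-s.d.
#'   units).
#' @export
consistency_check <- function(a, b, source = "peat", k = 1) {
  stopifnot(is.numeric(k), length(k) == 1L, k >= 0)
  ea <- .extract_ms(a, source, "first")
  eb <- .extract_ms(b, source, "second")
  pooled <- sqrt(ea$sd^2 + eb$sd^2)
  delta <- abs(ea$mean - eb$mean)
  structure(
    list(consistent = delta <= k * pooled, delta = delta,
         threshold = k * pooled, z = if (pooled > 0) delta / pooled else Inf,
         k = k, source = source),
    class = "consistency_report"
  )
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf("<consistency_report> f_%s: |delta| = %.4f %s %.4f (k = %g) -> %s\n",
              x$source, x$delta, if (x$consistent) "<=" else ">",
              x$threshold, x$k,
              if (x$consistent) "consistent" else "inconsistent"))
  invisible(x)
}
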