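POOL_VOCABULARY <- c("DIC", "DOC", "POC", "SOC", "ATM")

#' Read a measurement table
#'
#' Reads a CSV of isotopic pool measurements. Required columns: `site`,
#' `pool`, `d13c` (permil VPDB), `f14c` (fraction modern); optional:
#' `replicate`, `conc`, `depth`. The pool vocabulary is closed
#' (DIC, DOC, POC, SOC, ATM); unknown pools are rejected with their row
#' numbers - there is no silent coercion. Missing values are empty cells.
#'
#' @param path Path to a UTF-8, comma-separated file with a header row.
#' @return A validated data.frame of measurements.
#' @export
read_measurement_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_measurement_table(df, context = path)
}

#' @rdname read_measurement_table
#' @param df A data.frame in the measurement-table schema.
#' @param context Label used in error messages.
#' @export
validate_measurement_table <- function(df, context = "measurement table") {
  required <- c("site", "pool", "d13c", "f14c")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(context, ": missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) stop(context, ": empty table", call. = FALSE)
  for (col in c("d13c", "f14c", intersect(c("conc", "depth"), names(df)))) {
    v <- df[[col]]
    if (is.logical(v) && all(is.na(v))) {
      # an all-empty CSV column parses as logical NA
      df[[col]] <- as.numeric(v)
      next
    }
    if (is.character(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(!is.na(v) & nzchar(trimws(v)) & is.na(num))
      if (length(bad)) {
        stop(context, ": non-numeric '", col, "' value(s) in row(s) ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      df[[col]] <- num
    }
  }
  bad_pool <- which(!df$pool %in% POOL_VOCABULARY)
  if (length(bad_pool)) {
    stop(context, ": unknown pool '",
         paste(unique(df$pool[bad_pool]), collapse = "', '"),
         "' in row(s) ", paste(bad_pool, collapse = ", "),
         " (allowed: ", paste(POOL_VOCABULARY, collapse = ", "), ")",
         call. = FALSE)
  }
  bad_f <- which(!is.na(df$f14c) & df$f14c <= 0)
  if (length(bad_f)) {
    stop(context, ": non-positive f14c in row(s) ",
         paste(bad_f, collapse = ", "), call. = FALSE)
  }
  if (!"replicate" %in% names(df)) {
    df$replicate <- stats::ave(seq_len(nrow(df)),
                               df$site, df$pool, FUN = seq_along)
  }
  df
}

#' Write a measurement table
#'
#' Writes the CSV schema read by [read_measurement_table()], formatting
#' numeric tracer columns at full double precision (17 significant
#' digits) so that a write/read cycle is bit-identical.
#'
#' @param df Measurement data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_measurement_table <- function(df, path) {
  out <- df
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      v <- sprintf("%.17g", out[[col]])
      v[is.na(out[[col]])] <- ""
      out[[col]] <- v
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Summarize pools per site
#'
#' Per (site, pool) group: number of records and mean and sample standard
#' deviation (n - 1 denominator) of each tracer. Groups with a single
#' record report `NA` s.d. (flagged absent, not zero).
#'
#' @param df Measurement data.frame (schema of
#'   [read_measurement_table()]).
#' @param site,pool Optional filters; an empty selection is an error.
#' @return A data.frame with one row per (site, pool) and columns `n`,
#'   `d13c_mean`, `d13c_sd`, `f14c_mean`, `f14c_sd`.
#' @export
summarize_pools <- function(df, site = NULL, pool = NULL) {
  df <- validate_measurement_table(df)
  if (!is.null(site)) df <- df[df$site %in% site, , drop = FALSE]
  if (!is.null(pool)) df <- df[df$pool %in% pool, , drop = FALSE]
  if (nrow(df) == 0L) {
    stop("no measurements for the requested (site, pool) selection",
         call. = FALSE)
  }
  grp <- split(df, list(df$site, df$pool), drop = TRUE)
  out <- do.call(rbind, lapply(grp, function(g) {
    sd1 <- function(x) if (sum(is.finite(x)) > 1L)
      stats::sd(x, na.rm = TRUE) else NA_real_
    data.frame(
      site = g$site[1], pool = g$pool[1], n = nrow(g),
      d13c_mean = mean(g$d13c, na.rm = TRUE), d13c_sd = sd1(g$d13c),
      f14c_mean = mean(g$f14c, na.rm = TRUE), f14c_sd = sd1(g$f14c),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out[order(out$site, out$pool), , drop = FALSE]
}

# Config files: JSON always; YAML when the yaml package is installed.
.read_config <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML config requires the 'yaml' package; use JSON instead",
           call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
}

.end_members_from_config <- function(cfg_list) {
  lapply(cfg_list, function(em) {
    end_member(em$name, d13c = as.numeric(unlist(em$d13c)),
               f14c = as.numeric(unlist(em$f14c)))
  })
}

#' Build a scenario from a config list or file
#'
#' @param cfg A list (or path to a JSON/YAML file) with fields
#'   `true_fractions` (named), `end_members` (list of
#'   `{name, d13c: [mean, sd], f14c: [mean, sd]}`), and optionally
#'   `measurement_noise` (`{d13c:, f14c:}`), `n_replicates`, `seed`,
#'   `site`, `pool_map`, `outgassing_sources`, `target_source`.
#' @return A [scenario_spec()].
#' @export
scenario_from_config <- function(cfg) {
  if (is.character(cfg)) cfg <- .read_config(cfg)
  args <- list(
    true_fractions = unlist(cfg$true_fractions),
    end_members = .end_members_from_config(cfg$end_members)
  )
  for (f in c("measurement_noise", "n_replicates", "seed", "site",
              "pool_map", "outgassing_sources", "target_source")) {
    if (!is.null(cfg[[f]])) {
      args[[f]] <- if (f %in% c("measurement_noise", "pool_map",
                                "outgassing_sources"))
        unlist(cfg[[f]]) else cfg[[f]]
    }
  }
  do.call(scenario_spec, args)
}

#' Run the full source-apportionment pipeline
#'
#' Chains the complete analysis for one mixture: build the mixing
#' problems, run the Monte Carlo for the requested conceptual model(s),
#' check their consistency, combine them by inverse-variance weighting,
#' and optionally scale an areal CO2 flux to an annual source-attributed
#' carbon mass. Deterministic given the config seed: the equilibration
#' model runs with `seed`, the outgassing model with `seed + 1`.
#'
#' @param config A list (or path to JSON/YAML) with fields:
#'   * `end_members`: list of `{name, d13c: [mean, sd], f14c: [mean, sd]}`;
#'   * `mixture`: `{label, d13c: [mean, sd], f14c: [mean, sd]}`, or
#'     `{table: <csv path>, site: <site>}` to summarize a measured DIC
#'     pool;
#'   * `model`: `"equilibration"`, `"outgassing"` or `"both"` (default);
#'   * `n_iter` (default 100,000), `seed` (default 1);
#'   * `outgassing_sources` (default `c("peat", "modern")`),
#'     `target_source` (default `"peat"`);
#'   * optional `flux`: `{areal_flux: [lo, hi] or scalar, area,
#'     fraction}` - when `fraction` is omitted the combined (or
#'     single-model) mean is used.
#' @param keep_samples When `TRUE`, the full `posterior_summary` objects
#'   (with accepted-sample matrices) are attached as the
#'   `"posteriors_full"` attribute of the report.
#' @return A report list (class `peatmix_report`) with per-model
#'   posteriors (without sample matrices), consistency verdict, combined
#'   estimate, flux block, seed, constants and input provenance. Suitable
#'   for [jsonlite::write_json()].
#' @export
run_full_analysis <- function(config, keep_samples = FALSE) {
  if (is.character(config)) config <- .read_config(config)
  model <- if (is.null(config$model)) "both" else config$model
  stopifnot(model %in% c("both", "equilibration", "outgassing"))
  n_iter <- if (is.null(config$n_iter)) 100000L else as.integer(config$n_iter)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  target <- if (is.null(config$target_source)) "peat" else config$target_source
  out_src <- if (is.null(config$outgassing_sources)) c("peat", "modern")
             else unlist(config$outgassing_sources)

  ems <- .end_members_from_config(config$end_members)
  nm <- vapply(ems, `[[`, character(1), "name")
  mix_cfg <- config$mixture
  if (!is.null(mix_cfg$table)) {
    tab <- read_measurement_table(mix_cfg$table)
    s <- summarize_pools(tab, site = mix_cfg$site, pool = "DIC")
    mix <- mixture_obs(mix_cfg$site, d13c = c(s$d13c_mean, s$d13c_sd),
                       f14c = c(s$f14c_mean, s$f14c_sd))
  } else {
    mix <- mixture_obs(if (is.null(mix_cfg$label)) "mixture" else
                         mix_cfg$label,
                       d13c = as.numeric(unlist(mix_cfg$d13c)),
                       f14c = as.numeric(unlist(mix_cfg$f14c)))
  }

  posterior_block <- function(p) {
    list(model = p$model, fractions_mean = as.list(p$fractions_mean),
         fractions_sd = as.list(p$fractions_sd), n_iter = p$n_iter,
         n_accepted = p$n_accepted, acceptance_rate = p$acceptance_rate,
         seed = p$seed)
  }

  report <- list(
    package = "peatmix",
    model = model, n_iter = n_iter, seed = seed,
    target_source = target,
    constants = list(libby_mean_life_yr = LIBBY_MEAN_LIFE,
                     carbon_molar_mass_g_mol = CARBON_MOLAR_MASS,
                     days_per_year = DAYS_PER_YEAR),
    inputs = list(end_members = config$end_members,
                  mixture = list(label = mix$label,
                                 d13c = c(mix$d13c_mean, mix$d13c_sd),
                                 f14c = c(mix$f14c_mean, mix$f14c_sd)))
  )

  combined_mean <- NULL
  posteriors_full <- NULL
  if (model == "both") {
    res <- .run_model_pair(ems, mix, out_src, target, n_iter,
                           eq_seed = seed, out_seed = seed + 1)
    posteriors_full <- list(equilibration = res$eq, outgassing = res$out)
    report$posteriors <- list(equilibration = posterior_block(res$eq),
                              outgassing = posterior_block(res$out))
    report$consistency <- list(consistent = res$consistency$consistent,
                               delta = res$consistency$delta,
                               threshold = res$consistency$threshold,
                               k = res$consistency$k)
    report$combined <- list(source = target, mean = res$combined$mean,
                            sd = res$combined$sd,
                            weights = as.list(res$combined$weights),
                            sd_mode = res$combined$sd_mode)
    combined_mean <- res$combined$mean
  } else {
    srcs <- if (model == "outgassing") ems[match(out_src, nm)] else ems
    pr <- mixing_problem(model, srcs, mix)
    post <- run_monte_carlo(pr, n_iter = n_iter, seed = seed)
    posteriors_full <- stats::setNames(list(post), model)
    report$posteriors <- stats::setNames(list(posterior_block(post)), model)
    combined_mean <- unname(post$fractions_mean[[target]])
  }

  if (!is.null(config$flux)) {
    fl <- config$flux
    frac <- if (is.null(fl$fraction)) combined_mean else fl$fraction
    fluxes <- as.numeric(unlist(fl$areal_flux))
    masses <- vapply(fluxes, function(af) {
      annual_carbon_mass(af, fl$area, frac)$annual_mass
    }, numeric(1))
    report$flux <- list(areal_flux_mmol_m2_d = fluxes,
                        area_km2 = fl$area,
                        fraction = frac,
                        fraction_source = if (is.null(fl$fraction))
                          "combined estimate" else "config override",
                        annual_mass_gg_c = masses)
  }
  class(report) <- c("peatmix_report", "list")
  if (keep_samples) attr(report, "posteriors_full") <- posteriors_full
  report
}

#' @export
print.peatmix_report <- function(x, ...) {
  cat(sprintf("<peatmix_report> model = %s; seed = %d; n_iter = %d\n",
              x$model, x$seed, x$n_iter))
  for (nm in names(x$posteriors)) {
    p <- x$posteriors[[nm]]
    cat(sprintf("  %s: f_%s = %.3f +/- %.3f (acceptance %.1f%%)\n", nm,
                x$target_source, p$fractions_mean[[x$target_source]],
                p$fractions_sd[[x$target_source]],
                100 * p$acceptance_rate))
  }
  if (!is.null(x$combined)) {
    cat(sprintf("  combined: f_%s = %.3f +/- %.3f (%s)\n", x$target_source,
                x$combined$mean, x$combined$sd,
                if (x$consistency$consistent) "models consistent"
                else "models INCONSISTENT"))
  }
  if (!is.null(x$flux)) {
    cat(sprintf("  flux: %s Gg C yr^-1 over %s mmol m^-2 d^-1\n",
                paste(sprintf("%.0f", x$flux$annual_mass_gg_c),
                      collapse = "-"),
                paste(x$flux$areal_flux_mmol_m2_d, collapse = "-")))
  }
  invisible(x)
}
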