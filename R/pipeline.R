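#' Demo pipeline configuration (all-synthetic)
#'
#' A complete configuration exercising every analysis block on generated data:
#' a stabilised high-salt condition versus a marginal low-salt condition, a
#' chevron unfolding arm per condition, a model-free relaxation set, a toy
#' ion/salt-bridge ensemble, and an ortholog alignment with one covarying
#' pair. Use it as a template for configurations pointing at real CSV inputs.
#'
#' @param seed Integer seed used for every generator in the run.
#' @return A nested list understood by [run_pipeline()].
#' @export
demo_config <- function(seed = 1) {
  list(
    schema_version = 1,
    seed = seed,
    equilibrium = list(
      temperature_K = 303.15,
      urea_M = seq(0, 9, by = 0.5),
      noise_sd = 0.003,
      truth = list(m_eq = 5, bn_int = 1, bn_slope = -0.01,
                   bd_int = 0.2, bd_slope = 0.005),
      conditions = list(
        list(label = "low salt", ionic_strength_M = 0.0, dG0 = 4.4),
        list(label = "high salt", ionic_strength_M = 0.8, dG0 = 12.4)
      ),
      salt_series = list(dG0 = 4.4, m_salt = 9,
                         ionic_strength_M = c(0.005, 0.02, 0.08, 0.3, 0.8),
                         noise_sd = 0.1)
    ),
    kinetics = list(
      temperature_K = 303.15,
      urea_M = c(7, 7.5, 8, 8.5, 9),
      time_s = seq(0, 60, by = 0.25),
      amplitude = 1, offset = 0.2, noise_sd = 0.005,
      conditions = list(
        list(label = "low salt", ku0 = 0.088, m_ku = 0.177),
        list(label = "high salt", ku0 = 0.12, m_ku = 0.09)
      )
    ),
    nmr = list(
      tau_c_ns = 5.76,
      noise_sd = 0,
      residues = list(n = 8, S2_range = c(0.6, 0.95),
                      tau_e_ps_range = c(20, 200))
    ),
    trajectory = list(
      n_frames = 400, n_runs = 3,
      ion_targets = list(
        list(resno = 10, resid = "ASP", occupancy = 0.30),
        list(resno = 20, resid = "GLU", occupancy = 0.15),
        list(resno = 30, resid = "LYS", occupancy = 0.05)
      ),
      bridge_targets = list(
        list(lys_resno = 25, partner_resno = 42, partner_resid = "GLU",
             occupancy = 0.4)
      )
    ),
    sequence = list(
      n_seqs = 120, length = 30, charge_target = -10,
      covarying_pair = c(10, 22), n_permutations = 200
    )
  )
}

#' Validate a pipeline configuration
#'
#' Checks the configuration and returns every problem found (never just the
#' first).
#'
#' @param config Nested list or path to a YAML file.
#' @return Character vector of problems; empty when the config is valid.
#' @export
validate_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  problems <- character()
  need <- function(cond, msg) if (!isTRUE(cond)) problems <<- c(problems, msg)
  need(is.list(config), "config must be a list or YAML path")
  if (!is.list(config)) return(problems)
  need(!is.null(config$schema_version), "missing field: schema_version")
  blocks <- intersect(names(config),
                      c("equilibrium", "kinetics", "nmr", "trajectory", "sequence"))
  need(length(blocks) > 0, "no analysis blocks present")
  uses_generators <- any(purrr::map_lgl(blocks, function(b) {
    is.null(config[[b]]$file)
  }))
  if (uses_generators) {
    need(!is.null(config$seed), "missing field: seed (mandatory when generators are used)")
  }
  for (b in intersect(blocks, c("equilibrium", "kinetics"))) {
    need(!is.null(config[[b]]$temperature_K),
         sprintf("missing field: %s$temperature_K", b))
    need(!is.null(config[[b]]$conditions) && length(config[[b]]$conditions) >= 1,
         sprintf("missing field: %s$conditions", b))
  }
  if ("equilibrium" %in% blocks) {
    need(!is.null(config$equilibrium$urea_M), "missing field: equilibrium$urea_M")
    need(!is.null(config$equilibrium$truth), "missing field: equilibrium$truth")
  }
  if ("kinetics" %in% blocks) {
    need(!is.null(config$kinetics$urea_M), "missing field: kinetics$urea_M")
    need(!is.null(config$kinetics$time_s), "missing field: kinetics$time_s")
  }
  if ("nmr" %in% blocks) {
    need(!is.null(config$nmr$tau_c_ns), "missing field: nmr$tau_c_ns")
  }
  if ("trajectory" %in% blocks) {
    need(!is.null(config$trajectory$n_frames), "missing field: trajectory$n_frames")
  }
  if ("sequence" %in% blocks) {
    need(!is.null(config$sequence$covarying_pair),
         "missing field: sequence$covarying_pair")
  }
  problems
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes the requested blocks in dependency order (equilibrium before
#' kinetics, so the derived folding rates can use the fitted stabilities;
#' traces before arms within kinetics). All randomness is seeded from
#' `config$seed`, so reruns of the same configuration are reproducible. A
#' failure inside one block is recorded in the report and does not abort the
#' other blocks.
#'
#' @param config Nested list (see [demo_config()]) or path to a YAML file.
#' @return Object of class `run_report`: list with `provenance` (config hash,
#'   seed, package version) and one entry per executed block holding plain
#'   tibbles/values, plus `errors` for failed blocks.
#' @export
#' @examples
#' \donttest{
#' report <- run_pipeline(demo_config(seed = 7))
#' report$kinetics$salt_ddG
#' }
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  problems <- validate_pipeline_config(config)
  if (length(problems) > 0) {
    abort(paste0("Invalid pipeline configuration:\n",
                 paste0("  - ", problems, collapse = "\n")))
  }
  seed <- config$seed %||% 1
  report <- list(
    provenance = list(
      schema_version = config$schema_version,
      config_hash = rlang::hash(config),
      seed = seed,
      package_version = as.character(utils::packageVersion("saltfold"))
    ),
    errors = list()
  )
  run_block <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      report$errors[[name]] <<- conditionMessage(e)
      NULL
    })
    if (!is.null(res)) report[[name]] <<- res
  }

  eq_fits <- NULL
  if (!is.null(config$equilibrium)) {
    run_block("equilibrium", function() {
      cf <- config$equilibrium
      tr <- cf$truth
      fits <- purrr::imap(cf$conditions, function(cond, i) {
        curve <- sim_equilibrium_curve(
          dG0 = cond$dG0, m_eq = tr$m_eq,
          bn_int = tr$bn_int, bn_slope = tr$bn_slope,
          bd_int = tr$bd_int, bd_slope = tr$bd_slope,
          urea_M = unlist(cf$urea_M), temperature_K = cf$temperature_K,
          noise_sd = cf$noise_sd %||% 0, seed = seed + 100 + i
        )
        fit <- fit_equilibrium_curve(curve, temperature_K = cf$temperature_K)
        tibble(condition = cond$label,
               ionic_strength_M = cond$ionic_strength_M,
               dG0 = fit$dG0,
               dG0_se = fit$estimate$std_error[fit$estimate$term == "dG0"],
               m_eq = fit$m_eq,
               m_eq_se = fit$estimate$std_error[fit$estimate$term == "m_eq"],
               Cm = fit$Cm, rss = fit$rss)
      }) |> purrr::list_rbind()
      eq_fits <<- fits
      out <- list(fits = fits)
      if (!is.null(cf$salt_series)) {
        ss <- cf$salt_series
        series <- sim_salt_series(ss$dG0, ss$m_salt,
                                  unlist(ss$ionic_strength_M),
                                  ss$noise_sd %||% 0, seed = seed + 199)
        cmp <- compare_salt_models(series)
        out$salt_model_ranking <- as_tibble(cmp)
      }
      out
    })
  }

  if (!is.null(config$kinetics)) {
    run_block("kinetics", function() {
      cf <- config$kinetics
      summaries <- purrr::imap(cf$conditions, function(cond, i) {
        ks <- purrr::imap_dbl(unlist(cf$urea_M), function(u, j) {
          k_true <- cond$ku0 * exp(cond$m_ku * u)
          tr <- sim_unfolding_trace(
            k_u = k_true, amplitude = cf$amplitude, offset = cf$offset,
            time_s = unlist(cf$time_s), noise_sd = cf$noise_sd %||% 0,
            seed = seed + 1000 * i + j
          )
          fit_unfolding_trace(tr)$k_obs
        })
        arm <- fit_unfolding_arm(tibble(urea_M = unlist(cf$urea_M),
                                        ku_per_s = ks))
        if (!is.null(eq_fits)) {
          eq <- eq_fits[i, ]
          folding_summary(arm, dG0 = eq$dG0, m_eq = eq$m_eq,
                          temperature_K = cf$temperature_K,
                          dG0_se = eq$dG0_se, m_eq_se = eq$m_eq_se,
                          condition = cond$label)
        } else {
          tibble(condition = cond$label, ku0 = arm$ku0, ku0_se = arm$ku0_se,
                 m_ku = arm$m_ku, m_ku_se = arm$m_ku_se,
                 temperature_K = cf$temperature_K)
        }
      }) |> purrr::list_rbind()
      out <- list(summaries = summaries)
      if (nrow(summaries) >= 2 && "kf0" %in% names(summaries)) {
        lo <- summaries[1, ]; hi <- summaries[2, ]
        out$salt_ddG <- compute_salt_ddG(
          kf_low = lo$kf0, kf_high = hi$kf0,
          ku_low = lo$ku0, ku_high = hi$ku0,
          temperature_K = cf$temperature_K,
          ddG_DN_equilibrium = -(hi$dG0 - lo$dG0),
          kf_low_se = lo$kf0_se, kf_high_se = hi$kf0_se,
          ku_low_se = lo$ku0_se, ku_high_se = hi$ku0_se
        )
      }
      out
    })
  }

  if (!is.null(config$nmr)) {
    run_block("nmr", function() {
      cf <- config$nmr
      n <- cf$residues$n %||% 8
      truth <- tibble(
        residue = seq_len(n),
        S2 = seq(cf$residues$S2_range[1], cf$residues$S2_range[2],
                 length.out = n),
        tau_e_s = seq(cf$residues$tau_e_ps_range[1],
                      cf$residues$tau_e_ps_range[2], length.out = n) * 1e-12
      )
      rec <- sim_relaxation_set(truth, tau_c = cf$tau_c_ns * 1e-9,
                                noise_sd = cf$noise_sd %||% 0,
                                seed = seed + 300)
      fit <- fit_model2(rec)
      list(tau_c_ns = fit$tau_c_ns, params = fit$params,
           total_chisq = fit$total_chisq)
    })
  }

  if (!is.null(config$trajectory)) {
    run_block("trajectory", function() {
      cf <- config$trajectory
      ions <- if (!is.null(cf$ion_targets)) {
        purrr::map(cf$ion_targets, as_tibble) |> purrr::list_rbind()
      }
      bridges <- if (!is.null(cf$bridge_targets)) {
        purrr::map(cf$bridge_targets, as_tibble) |> purrr::list_rbind()
      }
      ens <- sim_toy_trajectory(
        ion_targets = ions, bridge_targets = bridges,
        n_frames = cf$n_frames, n_runs = cf$n_runs %||% 1,
        condition = cf$condition %||% "synthetic", seed = seed + 400
      )
      cs <- ion_contact_stats(ens, cutoff_A = cf$cutoff_A %||% 4)
      out <- list(ion_contacts = cs$per_residue, ion_counts = cs$global)
      if (!is.null(bridges)) {
        out$salt_bridges <- salt_bridge_fractions(
          ens, pairs = bridges[c("lys_resno", "partner_resno")],
          cutoff_A = cf$cutoff_A %||% 4
        )
      }
      out
    })
  }

  if (!is.null(config$sequence)) {
    run_block("sequence", function() {
      cf <- config$sequence
      aln <- sim_alignment(
        n_seqs = cf$n_seqs %||% 262, length = cf$length %||% 60,
        charge_target = cf$charge_target %||% -10,
        covarying_pair = unlist(cf$covarying_pair), seed = seed + 500
      )
      charges <- alignment_charge_stats(aln)
      cov <- covariation_mi(aln, n_permutations = cf$n_permutations %||% 1000,
                            seed = seed + 501)
      list(charge_summary = charges$summary,
           covariation = as_tibble(head(cov, 10)))
    })
  }

  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat("  blocks:", paste(setdiff(names(x), c("provenance", "errors")),
                         collapse = ", "), "\n")
  cat("  seed:", x$provenance$seed,
      " config hash:", x$provenance$config_hash, "\n")
  if (length(x$errors)) {
    cat("  failed blocks:", paste(names(x$errors), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' JSON is the canonical, lossless serialization (full double precision);
#' `format = "csv"` additionally writes one CSV per result table, including a
#' kinetics table shaped like the usual per-condition folding summary
#' (condition, ku, kf, beta_urea, phi_f_salt).
#'
#' @param report A [run_pipeline()] result.
#' @param dir Output directory (created if missing).
#' @param format `"json"` or `"csv"` (CSV implies JSON as well).
#' @return Paths of the files written, invisibly.
#' @export
write_report <- function(report, dir, format = c("json", "csv")) {
  stopifnot(inherits(report, "run_report"))
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, "report.json")
  jsonlite::write_json(unclass(report), paths, auto_unbox = TRUE, digits = NA,
                       null = "null")
  if (format == "csv") {
    tabs <- list()
    if (!is.null(report$equilibrium$fits)) {
      tabs$equilibrium_fits <- report$equilibrium$fits
    }
    if (!is.null(report$equilibrium$salt_model_ranking)) {
      tabs$salt_model_ranking <- report$equilibrium$salt_model_ranking
    }
    if (!is.null(report$kinetics$summaries)) {
      s <- report$kinetics$summaries
      t2 <- tibble(condition = s$condition, ku = s$ku0, kf = s$kf0,
                   beta_urea = s$beta_urea,
                   phi_f_salt = if (!is.null(report$kinetics$salt_ddG)) {
                     c(report$kinetics$salt_ddG$phi_f_salt,
                       rep(NA_real_, nrow(s) - 1))
                   } else {
                     rep(NA_real_, nrow(s))
                   })
      tabs$folding_summary <- t2
    }
    if (!is.null(report$trajectory$ion_contacts)) {
      tabs$ion_contacts <- report$trajectory$ion_contacts
      tabs$ion_counts <- report$trajectory$ion_counts
    }
    if (!is.null(report$trajectory$salt_bridges)) {
      tabs$salt_bridges <- report$trajectory$salt_bridges
    }
    if (!is.null(report$sequence$covariation)) {
      tabs$covariation <- report$sequence$covariation
    }
    for (nm in names(tabs)) {
      p <- file.path(dir, paste0(nm, ".csv"))
      write.csv(tabs[[nm]], p, row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

#' Reload a pipeline report written by [write_report()]
#'
#' @param path Path to `report.json`.
#' @return A `run_report` with tables restored as tibbles.
#' @export
read_report <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  restore <- function(x) {
    if (is.data.frame(x)) return(as_tibble(x))
    if (is.list(x)) return(purrr::map(x, restore))
    x
  }
  out <- restore(raw)
  class(out) <- "run_report"
  out
}
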