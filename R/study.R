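# End-to-end study runner: simulate both population-development approaches
# from one config, run diversity statistics, trials and genomic prediction,
# and compare simulated statistics with the closed-form expectations.

#' Default study configuration
#'
#' Population sizes default to one landrace of the experimental design
#' (LS = 48, DH = 471, GC = 274); genome, trait, trial and prediction
#' settings are desk-scale defaults that every field can override.
#'
#' @param ... overrides (same names as the returned list).
#' @return a named list (`study_config`).
#' @export
study_config <- function(...) {
  cfg <- list(
    seed = 1L,
    genome = list(n_chrom = 2L, markers_per_chrom = 400L,
                  chrom_length_cM = 160, chrom_length_bp = 160e6),
    pool_size = 400L,
    burnin = 10L,
    freq_spectrum = list(type = "beta_u"),
    private_fraction = 0.03,
    sizes = list(LS = 48L, DH = 471L, GC = 274L),
    trait = list(n_qtl = 100L, d12 = 0, d2x = 0, delta = 0, tester_d = 0),
    trials = list(E = 4L, R = 2L, target_h2 = 0.9),
    prediction = list(n_lines = 50L, reps = 3L, n_repeats = 2L, n_folds = 5L),
    census = list(n_gametes = 80L, n_reps = 20L),
    out_dir = NULL
  )
  utils::modifyList(cfg, list(...))
}

#' Read a study configuration from YAML
#' @param path YAML file; fields as in [study_config()].
#' @export
read_study_config <- function(path) {
  do.call(study_config, yaml::read_yaml(path))
}

write_output_csv <- function(df, path, cfg, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# gamecap seed=%d config=%s", seed, fingerprint(cfg)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run the full synthetic study
#'
#' Orchestrates the whole pipeline from one configuration: genetic map and
#' ancestral gamete pool, capture line, the landrace sample, DH (pure
#' approach) and GC-S0/S1 (admixed approach) populations, true genotypic
#' values and their closed-form expectations, molecular diversity
#' statistics, simulated multi-environment trials with variance components
#' and heritability, and a small within-population genomic-prediction
#' cross-validation for DH and GC.  Fully reproducible from the config's
#' master seed (stage seeds are derived with [split_seed()]).  If
#' `out_dir` is set, result tables are written as CSV with a seed /
#' config-fingerprint header line.  A failing stage raises an error naming
#' the stage; results of completed stages are attached to the error as
#' `partial`.
#'
#' @param config a list from [study_config()] / [read_study_config()].
#' @return a list bundle: `populations`, `trait`, `expectations`,
#'   `theory_vs_sim` (Table of expected vs simulated means/variances),
#'   `divstats`, `trials`, `prediction`, `config`.
#' @export
run_study <- function(config = study_config()) {
  cfg <- config
  seeds <- split_seed(cfg$seed, 12L)
  bundle <- list(config = cfg)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      err <- simpleError(sprintf("study stage '%s' failed: %s", name,
                                 conditionMessage(e)))
      err$partial <- bundle
      stop(err)
    })
  }

  bundle$map <- stage("genome", do.call(make_genetic_map, c(cfg$genome, list(seed = seeds[1]))))
  pool0 <- stage("pool", simulate_ancestral_pool(bundle$map, cfg$pool_size,
                                                 cfg$freq_spectrum, cfg$burnin,
                                                 seed = seeds[2]))
  cap <- stage("capture", make_capture_line(pool0, cfg$private_fraction,
                                            seed = seeds[3]))
  pool <- cap$pool
  capture <- cap$capture
  bundle$capture <- capture

  pops <- stage("populations", {
    ls_pop <- sample_plants(pool, min(cfg$sizes$LS, nrow(pool$gametes) %/% 2),
                            seed = seeds[4])
    dh <- derive_dh(pool, cfg$sizes$DH, seed = seeds[5])
    gc2 <- derive_gc(pool, capture, cfg$sizes$GC, seed = seeds[6])
    list(LS = ls_pop, DH = dh, GC_S0 = gc2$s0, GC_S1 = gc2$s1)
  })
  bundle$populations <- pops

  trait <- stage("trait", assign_trait(
    bundle$map, cfg$trait$n_qtl,
    dominance_spec = cfg$trait[c("d12", "d2x", "delta", "tester_d")],
    private_idx = capture$private_idx, seed = seeds[7]))
  bundle$trait <- trait
  p_qtl <- pool$p[trait$qtl]

  bundle$expectations <- stage("expectations",
                               expected_population_stats(trait, p_qtl))

  bundle$theory_vs_sim <- stage("theory_vs_sim", {
    val_ls <- genotypic_value_pp(pops$LS, trait)
    val_dh <- genotypic_value_pp(pops$DH, trait)
    val_gc <- genotypic_value_s12(pops$GC_S1, trait)
    exp_df <- as.data.frame(bundle$expectations)
    exp_pp <- exp_df[exp_df$level == "PP", ]
    sim <- data.frame(
      population = c("LS", "DH", "GC_S1_2"),
      sim_mean = c(mean(val_ls), mean(val_dh), mean(val_gc)),
      sim_var = c(stats::var(val_ls), stats::var(val_dh), stats::var(val_gc)))
    out <- merge(exp_pp[, c("population", "mean", "primary_var")], sim,
                 by = "population")
    out$delta_mean <- out$sim_mean - out$mean
    out$delta_var <- out$sim_var - out$primary_var
    out
  })

  bundle$divstats <- stage("divstats", {
    diag_loci <- capture$private_idx
    gd_cap <- if (length(diag_loci) > 0) {
      mean(apply(dose_matrix(pops$GC_S1)[, diag_loci, drop = FALSE], 1,
                 function(g) genetic_distance(g, rep(2, length(diag_loci)))))
    } else NA_real_
    census <- polymorphism_census(pops[c("LS", "DH", "GC_S1")],
                                  n_gametes = cfg$census$n_gametes,
                                  n_reps = cfg$census$n_reps, seed = seeds[8])
    list(
      allele_freq = data.frame(marker = bundle$map$marker, p_pool = pool$p,
                               f_LS = allele_frequencies(pops$LS),
                               f_DH = allele_frequencies(pops$DH),
                               f_GC = allele_frequencies(pops$GC_S1),
                               f_GC_expected = expected_gc_frequency(pool$p)),
      gd_gc_to_capture = gd_cap,
      census = census,
      molvar = lapply(pops[c("LS", "DH", "GC_S1")], molecular_variance),
      capture_proportion = capture_genome_proportion(pops$GC_S1,
        if (length(capture$private_idx)) capture$private_idx else seq_len(nrow(bundle$map)))
    )
  })

  bundle$trials <- stage("trials", {
    n_trial <- min(100L, pop_size(pops$DH), pop_size(pops$GC_S1))
    vals <- c(stats::setNames(genotypic_value_pp(pops$DH, trait)[seq_len(n_trial)],
                              sprintf("DH_%04d", seq_len(n_trial))),
              stats::setNames(genotypic_value_s12(pops$GC_S1, trait)[seq_len(n_trial)],
                              sprintf("GC_%04d", seq_len(n_trial))))
    td <- simulate_trials(vals, E = cfg$trials$E, R = cfg$trials$R,
                          target_h2 = cfg$trials$target_h2,
                          population = rep(c("DH", "GC"), each = n_trial),
                          seed = seeds[9])
    fit <- fit_variance_components(td)
    list(data = td, fit = fit,
         h2 = list(DH = entry_mean_heritability(fit, population = "DH"),
                   GC = entry_mean_heritability(fit, population = "GC")))
  })

  bundle$prediction <- stage("prediction", {
    blues <- bundle$trials$fit$blues
    mk <- function(popname, pop, vals_fun) {
      ids <- blues$entry[blues$population == popname]
      idx <- as.integer(sub(".*_", "", ids))
      g <- dose_matrix(pop)[idx, , drop = FALSE]
      rownames(g) <- ids
      list(geno = g, y = stats::setNames(blues$blue[match(ids, blues$entry)], ids),
           h2 = bundle$trials$h2[[popname]][["h2"]])
    }
    dat <- list(DH = mk("DH", pops$DH, NULL), GC = mk("GC", pops$GC_S1, NULL))
    lapply(names(dat), function(nm) {
      cv_within(dat[[nm]], n_lines = min(cfg$prediction$n_lines, nrow(dat[[nm]]$geno)),
                reps = cfg$prediction$reps, seed = seeds[10],
                n_folds = cfg$prediction$n_folds,
                n_repeats = cfg$prediction$n_repeats)
    }) -> cvs
    names(cvs) <- names(dat)
    cvs
  })

  if (!is.null(cfg$out_dir)) {
    stage("outputs", {
      dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
      write_output_csv(bundle$theory_vs_sim,
                       file.path(cfg$out_dir, "theory_vs_sim.csv"), cfg, cfg$seed)
      write_output_csv(bundle$divstats$allele_freq,
                       file.path(cfg$out_dir, "allele_frequencies.csv"), cfg, cfg$seed)
      write_output_csv(bundle$trials$fit$components,
                       file.path(cfg$out_dir, "variance_components.csv"), cfg, cfg$seed)
      cvdf <- do.call(rbind, lapply(names(bundle$prediction), function(nm) {
        data.frame(population = nm,
                   mean_rho = bundle$prediction[[nm]]$mean_rho,
                   q025 = bundle$prediction[[nm]]$q025,
                   q975 = bundle$prediction[[nm]]$q975)
      }))
      write_output_csv(cvdf, file.path(cfg$out_dir, "prediction_accuracy.csv"),
                       cfg, cfg$seed)
    })
  }
  bundle
}
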