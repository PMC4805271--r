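#' Build a run configuration
#'
#' Bundles input paths and the analysis parameters with their standard
#' defaults: cutoff grid 7-20 A (step 0.5), B-factor damping w = 0.01,
#' perturbation delta = 0.05, key fraction 5%, neighbor radius 7 A.
#'
#' @param free,bound paths to the ligand-free and ligand-bound PDB files.
#' @param chain chain identifier (default: first chain of the free file).
#' @param msa optional alignment path (aligned FASTA or Stockholm).
#' @param dssp optional DSSP output path for the free conformer.
#' @param sites optional active-site TSV path.
#' @param r_grid cutoff calibration grid, Angstrom.
#' @param w displacement damping scale.
#' @param delta perturbation magnitude.
#' @param fraction key-position fraction.
#' @param radius neighbor-averaging radius, Angstrom.
#' @param tol relative null-mode threshold.
#' @param use_experimental_b use experimental instead of theoretical
#'   B-factors in the displacement weighting.
#' @param rank_averaged rank key positions on the neighbor-averaged profile
#'   instead of the raw one.
#' @param seed integer seed.
#' @param outdir output directory (`NULL` = no files written).
#' @return a `run_config` list.
#' @export
run_config <- function(free, bound, chain = NULL, msa = NULL, dssp = NULL,
                       sites = NULL, r_grid = seq(7, 20, by = 0.5),
                       w = 0.01, delta = 0.05, fraction = 0.05, radius = 7,
                       tol = 1e-8, use_experimental_b = FALSE,
                       rank_averaged = FALSE, seed = 1, outdir = NULL) {
  stopifnot(w >= 0, abs(delta) <= 0.5, fraction > 0, fraction <= 1,
            radius > 0, all(r_grid > 0))
  structure(list(free = free, bound = bound, chain = chain, msa = msa,
                 dssp = dssp, sites = sites, r_grid = r_grid, w = w,
                 delta = delta, fraction = fraction, radius = radius,
                 tol = tol, use_experimental_b = use_experimental_b,
                 rank_averaged = rank_averaged, seed = as.integer(seed),
                 outdir = outdir),
            class = "run_config")
}

#' Read/write a run configuration as YAML
#'
#' @param path YAML file.
#' @return for `read_run_config`, a `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' @rdname read_run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

log_msg <- function(log, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
  message(msg)
  c(log, msg)
}

#' Run the full key-position analysis
#'
#' Orchestrates the stages: read and superpose the conformer pair, calibrate
#' the cutoff on experimental B-factors, build both conformers' elastic
#' networks, construct the weighted conformational-change vector and its mode
#' subspace S, scan all residues with spring perturbations, select key
#' positions, and (when inputs are given) score conservation and run the
#' characterization analyses. Reports are written to `config$outdir` as TSV
#' plus one JSON summary.
#'
#' @param config a [run_config()].
#' @return list of stage results (`pair`, `qc`, `calibration`, `modes`,
#'   `expansion`, `subspace`, `scores`, `keys`, optional `conservation`,
#'   `characterization`), invisibly.
#' @export
run_pipeline <- function(config) {
  log <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  log <- log_msg(log, "confkeys ", as.character(utils::packageVersion(
    "confkeys")), "; w=", config$w, " delta=", config$delta,
    " fraction=", config$fraction, " radius=", config$radius)

  free <- stage("read", read_ca_structure(config$free, config$chain))
  bound <- stage("read", read_ca_structure(config$bound, config$chain))
  pair <- stage("superpose", pair_and_superpose(free, bound))
  log <- log_msg(log, "pair: ", nrow(pair$mapping), " mapped residues, RMSD ",
                 round(pair$rmsd, 3), " A")

  cal <- stage("calibrate",
               calibrate_cutoff(free, config$free, grid = config$r_grid))
  log <- log_msg(log, "calibrated r_c = ", cal$r_c, " A (Spearman ",
                 round(cal$spearman, 3), ")")

  model_f <- stage("enm", build_enm(free, config$free, cal$r_c))
  model_b <- stage("enm", build_enm(bound, config$bound, cal$r_c))
  modes_f <- stage("enm", enm_modes(model_f, config$tol))
  modes_b <- stage("enm", enm_modes(model_b, config$tol))

  bf <- if (config$use_experimental_b) free$bfactor
        else theoretical_bfactors(modes_f, scale_to = free$bfactor)
  bb <- if (config$use_experimental_b) bound$bfactor
        else theoretical_bfactors(modes_b, scale_to = bound$bfactor)
  v <- stage("modespace", weighted_difference(pair, bf, bb, config$w))
  expn <- stage("modespace", expand_on_modes(v, modes_f))
  S <- select_subspace(expn, modes_f, "S")
  log <- log_msg(log, "subspace S: P_q = ", round(expn$p, 3), ", M = ",
                 expn$m)

  scores <- stage("scan",
                  scan_all_residues(model_f, modes_f, S, config$delta))
  rank_profile <- if (config$rank_averaged)
    neighbor_average(scores$zscore_s, free, config$radius)
    else scores$zscore_s
  keys <- select_key_positions(rank_profile, config$fraction)
  log <- log_msg(log, "key positions (", keys$count, "): ",
                 paste(free$resno[keys$indices], collapse = ", "))

  conservation <- NULL
  n_homologs <- NA_integer_
  msa_cov <- NA_real_
  if (!is.null(config$msa)) {
    conservation <- stage("conservation", {
      aln <- read_msa(config$msa)
      aln <- filter_alignment(aln)
      n_homologs <- attr(aln, "n_homologs")
      mapping <- map_alignment(aln, free)
      msa_cov <- mean(aln$ali[aln$ref, ] != "-")
      wts <- henikoff_weights(aln)
      idx <- conservation_index(aln, wts)
      prof <- zscore_evolution(idx, mapping)
      zs_avg <- neighbor_average(scores$zscore_s, free, config$radius)
      ze_avg <- neighbor_average(prof$zscore_evol, free, config$radius)
      corr <- correlate_scores(zs_avg, ze_avg)
      list(profile = prof, correlation = corr, n_homologs = n_homologs)
    })
    log <- log_msg(log, "conservation: rho = ",
                   round(conservation$correlation$rho, 3), " (p = ",
                   signif(conservation$correlation$p, 3), ")")
  } else {
    log <- log_msg(log, "no MSA supplied: conservation stage skipped")
  }

  characterization <- NULL
  if (!is.null(config$dssp) || !is.null(config$sites)) {
    characterization <- stage("characterize", {
      out <- list()
      contacts <- suppressWarnings(
        detect_contacts(free, config$free, cal$r_c))
      out$incidence_aa <- incidence_amino_acid(keys, free)
      if (!is.null(config$dssp)) {
        dssp <- read_dssp(config$dssp, unique(free$chain))
        if (nrow(dssp) == length(free$resno)) {
          out$incidence_sse <- incidence_sse(keys, dssp$sse)
          out$incidence_inter_sse <-
            incidence_inter_sse(keys, dssp$sse, contacts)
          out$rsa <- rsa_from_dssp(dssp)
        }
      }
      if (!is.null(config$sites)) {
        sites <- read_site_list(config$sites, free)
        out$site_distance <- active_site_distance(free, sites)
      }
      out
    })
  }

  qc <- qc_pair(pair, bfactor_spearman = cal$spearman,
                msa_coverage = msa_cov, n_homologs = n_homologs)

  res <- list(pair = pair, qc = qc, calibration = cal, model = model_f,
              modes = modes_f, expansion = expn, subspace = S,
              scores = scores, keys = keys, conservation = conservation,
              characterization = characterization, log = log,
              config = config)
  if (!is.null(config$outdir)) write_reports(res, config$outdir)
  invisible(res)
}

# write the TSV/JSON report bundle for a pipeline result
write_reports <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg <- res$config
  free <- res$pair$free
  write_pair_report(res$pair, file.path(outdir, "pair_report.tsv"))
  utils::write.table(res$calibration$curve,
                     file.path(outdir, "calibration.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_mode_table(res$modes, file.path(outdir, "modes.tsv"))
  write_subspace_report(res$expansion, res$modes,
                        file.path(outdir, "subspace.tsv"))
  write_score_table(res$scores, free, res$keys,
                    file.path(outdir, "scores.tsv"), cfg$radius)
  summary <- list(
    parameters = list(r_c = res$calibration$r_c, w = cfg$w,
                      delta = cfg$delta, fraction = cfg$fraction,
                      radius = cfg$radius, seed = cfg$seed),
    qc = as.list(setNames(res$qc$pass, res$qc$criterion)),
    rmsd = res$pair$rmsd,
    p_q = res$expansion$p, m = res$expansion$m,
    subspace_modes = res$subspace$modes,
    key_positions = free$resno[res$keys$indices],
    calibration_spearman = res$calibration$spearman)
  if (!is.null(res$conservation))
    summary$conservation <- res$conservation$correlation
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(res$log, file.path(outdir, "run.log"))
  invisible(outdir)
}

#' Generate a fixture, run the pipeline on it, and report ground-truth
#' recovery
#'
#' Writes a seeded synthetic fixture (with a coupled MSA) to disk, runs the
#' full pipeline through the public file readers, and measures how well each
#' stage recovers the planted ground truth: the planted-mode subspace, the
#' hinge location of the two-domain topology, and the sign of the
#' conservation coupling.
#'
#' @param spec a [fixture_spec()].
#' @param outdir output directory for fixture files and reports.
#' @param ... parameter overrides passed to [run_config()].
#' @return list with `result` (pipeline output) and `recovery` (named list:
#'   `planted_recovered`, `subspace_zeta`, `hinge_enrichment`,
#'   `conservation_rho`).
#' @export
run_synth <- function(spec, outdir = tempfile("confkeys-synth-"), ...) {
  fix <- synth_fixture(spec)
  # a provisional scan on the generating network supplies the score profile
  # the coupled MSA needs
  expn0 <- expand_on_modes(
    weighted_difference(pair_and_superpose(fix$free, fix$bound),
                        theoretical_bfactors(fix$modes),
                        theoretical_bfactors(fix$modes), w = 0),
    fix$modes)
  S0 <- select_subspace(expn0, fix$modes)
  scores0 <- scan_all_residues(fix$model, fix$modes, S0, 0.05)
  msa <- make_coupled_msa(aa_three_to_one(fix$free$aa), scores0$zscore_s,
                          coupling = fix$spec$msa$coupling,
                          n_rows = fix$spec$msa$n_rows,
                          noise_sd = fix$spec$msa$noise_sd,
                          seed = fix$spec$seed + 401L)
  paths <- write_fixture(fix, outdir, msa = msa)
  cfg <- run_config(free = paths[["free"]], bound = paths[["bound"]],
                    msa = paths[["msa"]], seed = fix$spec$seed,
                    outdir = file.path(outdir, "reports"), ...)
  res <- run_pipeline(cfg)

  planted <- sort(fix$spec$planted_modes)
  recovered <- sort(res$subspace$modes)
  n_hinge <- length(fix$hinge)
  hinge_enrichment <- if (n_hinge) {
    frac_keys <- mean(res$keys$indices %in% fix$hinge)
    frac_keys / (n_hinge / length(fix$free$resno))
  } else NA_real_
  recovery <- list(
    planted_recovered = identical(planted, recovered),
    p_q = res$expansion$p,
    hinge_enrichment = hinge_enrichment,
    conservation_rho = if (!is.null(res$conservation))
      res$conservation$correlation$rho else NA_real_)
  jsonlite::write_json(recovery, file.path(outdir, "recovery.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(result = res, recovery = recovery, paths = paths)
}
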