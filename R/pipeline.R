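#' End-to-end pipeline configuration
#'
#' Drives the full workflow — descriptors, pharmacophore fits, contact
#' fingerprints, matrix assembly, train/test split, GA feature selection
#' with a learner, validation, pharmacophore screening and hit ranking —
#' on a self-generated synthetic bundle (or user-supplied pharmacophore
#' files). Everything downstream of `seed` is deterministic.
#'
#' @param seed integer master seed.
#' @param out_dir output directory (created if needed).
#' @param phore_paths character vector of PHORE model files; defaults to
#'   the three fixtures shipped with the package.
#' @param n_compounds modelled compound count.
#' @param match_fraction fraction of compounds planted as pharmacophore
#'   hits.
#' @param noise_sd activity noise (log units).
#' @param learner "MLR", "SVR" or "RF".
#' @param ga a [ga_settings()]; the default here is scaled down from the
#'   classical population-200 / 1000-generation search so a desk-scale
#'   run finishes in seconds.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("phoreqsar_run_"),
                            phore_paths = NULL, n_compounds = 40L,
                            match_fraction = 0.6, noise_sd = 0.1,
                            learner = "MLR",
                            ga = ga_settings(population_size = 60L,
                                             max_generations = 15L,
                                             seed = seed)) {
  if (is.null(phore_paths))
    phore_paths <- system.file("extdata",
                               c("hypo_5-R2-08.phore", "hypo_6-R2-07.phore",
                                 "hypo_8-R3-08.phore"),
                               package = "phoreqsar")
  list(seed = as.integer(seed), out_dir = out_dir,
       phore_paths = phore_paths, n_compounds = as.integer(n_compounds),
       match_fraction = match_fraction, noise_sd = noise_sd,
       learner = learner, ga = ga)
}

#' Run the full pipeline
#'
#' Executes nine stages in order, logging one line per stage with its
#' row counts, and writes every intermediate table plus a JSON run
#' manifest (config snapshot, seed, per-stage outputs, file digests) to
#' `config$out_dir`. Re-running an identical config reproduces identical
#' file digests.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress stage logging.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(stage, msg) {
    if (!quiet) message(sprintf("[%s] %s", stage, msg))
  }
  paths <- list()
  save_tsv <- function(df, name) {
    p <- file.path(config$out_dir, name)
    write_compound_tsv(df, p)
    p
  }

  ## 1: inputs --------------------------------------------------------
  models <- lapply(config$phore_paths, read_pharmacophore)
  names(models) <- vapply(models, `[[`, "", "name")
  sim <- sim_config(seed = config$seed, n_compounds = config$n_compounds,
                    noise_sd = config$noise_sd)
  pocket <- gen_pocket(sim)
  ligands <- gen_ligands(sim, models[[1]], config$match_fraction)
  site_keys <- pocket$key[seq_len(min(12L, nrow(pocket)))]
  contact_keys <- .with_seed(config$seed + 606L, {
    lapply(stats::setNames(names(ligands), names(ligands)), function(id)
      site_keys[stats::runif(length(site_keys)) < 0.4])
  })
  poses <- gen_poses(sim, pocket, ligands, contact_keys)
  pdb_path <- file.path(config$out_dir, "pocket.pdb")
  write_pdb(pocket, pdb_path)
  sdf_path <- file.path(config$out_dir, "ligands.sdf")
  write_sdf(ligands, sdf_path)
  paths$inputs <- c(pdb_path, sdf_path)
  log_stage("inputs", sprintf("%d pharmacophores, %d pocket atoms, %d ligands",
                              length(models), nrow(pocket), length(ligands)))

  ## 2: physicochemical descriptors -----------------------------------
  phys <- descriptor_table(ligands)
  paths$descriptors <- save_tsv(phys, "physchem.tsv")
  log_stage("descriptors", sprintf("%d compounds x %d descriptors",
                                   nrow(phys), ncol(phys) - 1L))

  ## 3: pharmacophore fit values --------------------------------------
  fits <- data.frame(compound_id = names(ligands))
  for (nm in names(models))
    fits[[nm]] <- fit_descriptors(ligands, models[[nm]])
  paths$fits <- save_tsv(fits, "fits.tsv")
  log_stage("fits", sprintf("%d compounds x %d models", nrow(fits),
                            length(models)))

  ## 4: contact fingerprints ------------------------------------------
  lrcf <- build_lrcf_matrix(pocket, poses)
  paths$lrcf <- save_tsv(lrcf, "lrcf.tsv")
  log_stage("lrcf", sprintf("%d compounds x %d contact bits", nrow(lrcf),
                            ncol(lrcf) - 1L))

  ## 5: assemble -------------------------------------------------------
  support <- c(1.0, 0.8, 0.6)
  names(support) <- c(names(models)[1],
                      names(lrcf)[2],   # first contact column
                      "CHI_2")
  sim$true_support <- support
  pre <- assemble_matrix(fits, lrcf, phys,
                         data.frame(compound_id = names(ligands),
                                    log_inv_ic50 = 0))
  activities <- gen_activities(pre, sim)
  dm <- assemble_matrix(fits, lrcf, phys, activities)
  paths$assemble <- save_tsv(
    data.frame(compound_id = dm$ids, dm$values, check.names = FALSE),
    "matrix.tsv")
  log_stage("assemble", sprintf("%d x %d matrix (%s)", length(dm$ids),
                                ncol(dm$values),
                                paste(dm$blocks, collapse = "+")))

  ## 6: split ----------------------------------------------------------
  split <- split_train_test(dm)
  paths$split <- save_tsv(
    data.frame(compound_id = c(split$train, split$test),
               role = rep(c("train", "test"),
                          c(length(split$train), length(split$test)))),
    "split.tsv")
  log_stage("split", sprintf("%d train / %d test", length(split$train),
                             length(split$test)))

  ## 7: GFA feature selection -----------------------------------------
  spec <- regressor_spec(config$learner, seed = config$seed)
  sel <- gfa_select(dm, spec, config$ga, ids = split$train)
  paths$gfa <- file.path(config$out_dir, "gfa_trace.tsv")
  utils::write.table(sel$trace, paths$gfa, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  log_stage("gfa", sprintf("selected %d descriptors, fitness %.3f",
                           length(sel$subset), sel$fitness))

  ## 8: validate -------------------------------------------------------
  report <- validate_model(dm, split, sel$subset, spec)
  paths$validate <- file.path(config$out_dir, "validation.tsv")
  utils::write.table(
    data.frame(r2_resub = report$r2_resub, r2_l20 = report$r2_l20,
               r2_loo = report$r2_loo, r2_press = report$r2_press),
    paths$validate, sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage("validate", sprintf("r2 %.3f | q2_L20 %.3f | q2_LOO %.3f | r2_PRESS %.3f",
                                report$r2_resub, report$r2_l20,
                                report$r2_loo, report$r2_press))

  ## 9: screen + rank --------------------------------------------------
  hits_per_model <- lapply(models, function(m)
    names(ligands)[vapply(ligands, function(lg)
      screen_molecule(lg, m)$hit, logical(1))])
  unique_hits <- dedupe_hits(hits_per_model)
  preds <- if (length(unique_hits)) {
    X <- dm$values[match(unique_hits, dm$ids), report$selected_descriptors,
                   drop = FALSE]
    stats::setNames(predict(report$model, X), unique_hits)
  } else stats::setNames(numeric(0), character(0))
  ranked <- rank_and_filter_hits(preds)
  paths$screen <- save_tsv(ranked, "hits.tsv")
  log_stage("screen", sprintf("per-model hits %s -> %d unique -> %d retained",
                              paste(lengths(hits_per_model), collapse = "/"),
                              length(unique_hits), nrow(ranked)))

  manifest <- list(
    version = as.character(utils::packageVersion("phoreqsar")),
    seed = config$seed,
    config = config[setdiff(names(config), "ga")],
    ga = unclass(config$ga),
    stages = lapply(paths, normalizePath),
    digests = as.list(tools::md5sum(unlist(paths))))
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
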