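# tract dictionary: commissural segments are midline, every other family is
# bilateral
commissural_tracts <- c("CC_1", "CC_2", "CC_5", "CC_6", "CC_7")
bilateral_families <- c("ATR", "CG", "CST", "FPT", "ILF", "SLF_I", "SLF_II",
                        "SLF_III", "ST_PREM", "STR", "T_PREM", "UF")

#' Expand tract families to concrete bundle names
#'
#' Corpus-callosum segments are midline structures and map to themselves;
#' all other families expand to `_left` and `_right` bundles. The default
#' selection (5 commissural segments + 12 bilateral families) yields the 29
#' bundles of interest grouped into commissural, association, projection,
#' thalamic and striatal pathways.
#'
#' @param families Character vector of family names (default: the full
#'   configured dictionary).
#' @return Sorted character vector of bundle names.
#' @examples
#' length(expand_tract_list()) # 29
#' expand_tract_list("ATR")    # ATR_left, ATR_right
#' @export
expand_tract_list <- function(families = c(commissural_tracts,
                                           bilateral_families)) {
  known <- c(commissural_tracts, bilateral_families)
  bad <- setdiff(families, known)
  if (length(bad)) {
    stop("unknown tract family: ", paste(bad, collapse = ", "),
         "\nvalid families: ", paste(sort(known), collapse = ", "),
         call. = FALSE)
  }
  out <- unlist(lapply(families, function(f) {
    if (f %in% commissural_tracts) f else paste0(f, c("_left", "_right"))
  }))
  sort(unique(out))
}

#' Pipeline configuration
#'
#' All stage parameters of the end-to-end pipeline, with one master seed
#' from which each stage derives its own stream (so stages can be re-run
#' independently yet reproducibly).
#'
#' @param tracts Tract families (see [expand_tract_list()]).
#' @param nodes Centroid nodes per bundle.
#' @param max_compartments Largest zeppelin count tried per voxel.
#' @param d_iso Free-water diffusivity, mm^2/s.
#' @param prune_threshold,var_target,alpha,n_perm Statistics parameters
#'   (see [alongtract_group_test()]). `n_perm` defaults to 1000 for the
#'   bundled demo; production analyses typically use 10000.
#' @param covariates Covariate columns removed before testing.
#' @param seed Master integer seed.
#' @param sim Synthetic-demo sizes: a list with `n_group1, n_group2,
#'   effects, aes_effects, snr, phantom_dim`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(tracts = c(commissural_tracts, bilateral_families),
                            nodes = 100, max_compartments = 3, d_iso = 3.0e-3,
                            prune_threshold = 0.8, var_target = 0.8,
                            alpha = 0.05, n_perm = 1000,
                            covariates = c("age", "sex", "center"),
                            seed = 1,
                            sim = list()) {
  expand_tract_list(tracts)  # validates names
  stopifnot(nodes >= 2, alpha > 0, alpha < 1, n_perm >= 1,
            prune_threshold > 0, var_target > 0, var_target <= 1)
  sim_defaults <- list(
    n_group1 = 21, n_group2 = 35,
    effects = list(list(pc = 1, nodes = 40:60, d = 1.0)),
    aes_effects = list(list(pc = 1, nodes = 40:60, slope = -12)),
    snr = 30, phantom_dim = c(4, 4, 1)
  )
  for (nm in names(sim)) sim_defaults[[nm]] <- sim[[nm]]
  sim <- sim_defaults
  structure(list(tracts = tracts, nodes = nodes,
                 max_compartments = max_compartments, d_iso = d_iso,
                 prune_threshold = prune_threshold, var_target = var_target,
                 alpha = alpha, n_perm = n_perm, covariates = covariates,
                 seed = as.integer(seed), sim = sim),
            class = "pipeline_config")
}

write_json_stable <- function(x, file) {
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}

#' Run the full synthetic end-to-end pipeline
#'
#' Exercises every stage on synthetic inputs: (1) simulate a gradient
#' scheme and a two-region phantom (free water + single fiber) and fit the
#' mixture model per voxel; (2) simulate a geometric bundle, write it to
#' TRK, compute its centroid and project the fitted metric maps into a
#' bundle profile; (3) simulate a group bundle-profile dataset with a
#' planted effect and run the along-tract group and association analyses.
#' Stage outputs are written in a fixed layout under `out_dir`; a run
#' manifest records the configuration, versions, per-stage timing and
#' output checksums. Result tables and the results JSON are byte-identical
#' across reruns with the same config and seed (the manifest itself carries
#' timing and is excluded from that guarantee).
#'
#' When `input_dir` contains `profiles.tsv` and `metadata.tsv`, those are
#' used for the statistics stage instead of simulated profiles.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created).
#' @param input_dir Optional directory with user-supplied profile inputs.
#' @return List: `out_dir`, `results` (named file paths), `group_result`,
#'   `assoc_result`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         input_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  timing <- list()
  warnings_log <- character()
  paths <- c()
  run_stage <- function(name, expr) {
    st <- Sys.time()
    out <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
             call. = FALSE)
      }),
      warning = function(w) {
        warnings_log <<- c(warnings_log,
                           sprintf("[%s] %s", name, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    timing[[name]] <<- round(as.numeric(difftime(Sys.time(), st, units = "secs")), 3)
    out
  }

  # --- stage 1: scheme + phantom + model fit -------------------------------
  mcm <- run_stage("fit-mcm", {
    scheme <- gen_scheme(seed = derive_seed(config$seed, 1L))
    write_scheme_fsl(scheme, file.path(out_dir, "scheme.bval"),
                     file.path(out_dir, "scheme.bvec"))
    paths["bval"] <- file.path(out_dir, "scheme.bval")
    paths["bvec"] <- file.path(out_dir, "scheme.bvec")
    dd <- config$sim$phantom_dim
    csf <- array(FALSE, dd); csf[seq_len(floor(dd[1] / 2)), , ] <- TRUE
    fib <- array(FALSE, dd); fib[(floor(dd[1] / 2) + 1):dd[1], , ] <- TRUE
    spec <- phantom_spec(
      dim = dd, voxel_size = c(2, 2, 2),
      regions = list(
        list(mask = csf, fit = mcm_fit(1, d_iso = config$d_iso)),
        list(mask = fib,
             fit = mcm_fit(0.15, list(zeppelin(0.85, c(1, 0, 0), 1.7e-3, 0.3e-3)),
                           d_iso = config$d_iso))
      ),
      snr = config$sim$snr, seed = derive_seed(config$seed, 2L))
    ph <- gen_phantom(spec, scheme)
    fitted <- fit_volume(ph$dwi, ph$mask, scheme,
                         fit_config(d_iso = config$d_iso,
                                    max_compartments = config$max_compartments,
                                    seed = derive_seed(config$seed, 3L)))
    maps <- write_metric_maps(fitted, ph$affine, file.path(out_dir, "maps"))
    paths <- c(paths, maps)
    list(phantom = ph, fitted = fitted, scheme = scheme)
  })

  # --- stage 2: bundle + tractometry ---------------------------------------
  tracto <- run_stage("tractometry", {
    dd <- config$sim$phantom_dim
    b <- gen_bundle("line", n_streamlines = 12, jitter_sd = 0.2,
                    seed = derive_seed(config$seed, 4L),
                    n_points = 40, scale = 2 * (dd[1] - 1), spread_sd = 0.3,
                    offset = c(0, 2, 0), name = "demo_line")
    trk <- file.path(out_dir, "demo_line.trk")
    write_trk(b, trk, affine = mcm$phantom$affine, dim = dd,
              voxel_size = c(2, 2, 2))
    paths["trk"] <- trk
    b2 <- read_bundle(trk)
    prof <- build_subject_profiles(mcm$fitted$metrics, mcm$phantom$affine,
                                   list(b2), subject_id = "phantom01",
                                   s = min(config$nodes, 20),
                                   config = projection_config(min_streamlines = 1))
    f <- file.path(out_dir, "profiles_phantom.tsv")
    write_profiles(prof, f)
    paths["profiles_phantom"] <- f
    prof
  })

  # --- stage 3: group statistics -------------------------------------------
  stats_out <- run_stage("stats", {
    if (!is.null(input_dir) &&
        file.exists(file.path(input_dir, "profiles.tsv")) &&
        file.exists(file.path(input_dir, "metadata.tsv"))) {
      profiles <- read_profiles(file.path(input_dir, "profiles.tsv"))
      meta <- read_metadata(file.path(input_dir, "metadata.tsv"))
      truth <- NULL
    } else {
      sim <- gen_profiles(profile_sim_spec(
        n_group1 = config$sim$n_group1, n_group2 = config$sim$n_group2,
        n_nodes = config$nodes,
        effects = config$sim$effects, aes_effects = config$sim$aes_effects,
        seed = derive_seed(config$seed, 5L)))
      profiles <- sim$profiles
      meta <- sim$meta
      truth <- sim$truth
    }
    missing <- setdiff(config$covariates, names(meta))
    if (length(missing)) {
      stop("metadata lacks covariate column(s): ",
           paste(missing, collapse = ", "))
    }
    write_profiles(profiles, file.path(out_dir, "profiles.tsv"))
    write_metadata(meta, file.path(out_dir, "metadata.tsv"))
    paths["profiles"] <- file.path(out_dir, "profiles.tsv")
    paths["metadata"] <- file.path(out_dir, "metadata.tsv")

    bname <- unique(profiles$bundle)[1]
    grp <- alongtract_group_test(profiles, meta, bundle = bname,
                                 prune_threshold = config$prune_threshold,
                                 var_target = config$var_target,
                                 covariates = config$covariates,
                                 alpha = config$alpha, n_perm = config$n_perm,
                                 seed = derive_seed(config$seed, 6L))
    assoc <- alongtract_association(profiles, meta, bundle = bname,
                                    prune_threshold = config$prune_threshold,
                                    var_target = config$var_target,
                                    covariates = config$covariates,
                                    alpha = config$alpha, n_perm = config$n_perm,
                                    seed = derive_seed(config$seed, 7L))
    readr::write_tsv(tidy(grp), file.path(out_dir, "group_results.tsv"))
    readr::write_tsv(tidy(assoc), file.path(out_dir, "association_results.tsv"))
    pca_report <- dplyr::left_join(tidy(grp$pc_model),
                                   tibble::tibble(
                                     component = paste0("PC", seq_along(grp$pc_model$explained_variance_ratio)),
                                     variance_ratio = grp$pc_model$explained_variance_ratio),
                                   by = "component")
    readr::write_tsv(pca_report, file.path(out_dir, "pca_report.tsv"))
    paths["group_results"] <- file.path(out_dir, "group_results.tsv")
    paths["association_results"] <- file.path(out_dir, "association_results.tsv")
    paths["pca_report"] <- file.path(out_dir, "pca_report.tsv")

    results <- list(
      bundle = bname,
      group = list(fwe_cluster_size = grp$fwe_cluster_size,
                   n_significant_nodes = sum(grp$table$significant),
                   p_fwe = grp$p_fwe, L = grp$pc_model$L,
                   retained_metrics = grp$pruning$retained),
      association = list(fwe_cluster_size = assoc$fwe_cluster_size,
                         n_significant_nodes = sum(assoc$table$significant),
                         p_fwe = assoc$p_fwe),
      n_perm = config$n_perm, alpha = config$alpha, seed = config$seed
    )
    write_json_stable(results, file.path(out_dir, "results.json"))
    paths["results"] <- file.path(out_dir, "results.json")
    list(group = grp, assoc = assoc, results = results, truth = truth)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("alongtract")),
    config = unclass(config),
    timing_sec = timing,
    total_sec = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3),
    warnings = warnings_log,
    checksums = as.list(tools::md5sum(unname(paths[file.exists(paths)])))
  )
  write_json_stable(manifest, file.path(out_dir, "run_manifest.json"))

  invisible(list(out_dir = out_dir, results = paths,
                 group_result = stats_out$group, assoc_result = stats_out$assoc,
                 manifest = manifest))
}
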