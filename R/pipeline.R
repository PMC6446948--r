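#' Pipeline run configuration
#'
#' Bundles every choice of a full study-design run: data source, model-order
#' list, networks of interest and control networks, back-reconstruction
#' methods, template source, optional nuisance regression, permutation count
#' and seeds.
#'
#' @param generator A [generator_config()] (used when `data_dir` is `NULL`).
#' @param data_dir Optional directory of a written cohort (see
#'   [write_cohort()]) to load instead of generating.
#' @param mo_list List of model orders; integers and/or `"auto"`.
#' @param networks Names of the networks of interest.
#' @param control_networks Names of control networks (analyzed identically).
#' @param methods Back-reconstruction routes to run.
#' @param template_source `"sample_specific"` (select group components by
#'   matching the generator's reference maps) or a named list of NIfTI paths
#'   to external reference maps.
#' @param nuisance_regression Logical; regress WM/CSF-style confounds before
#'   analysis (generated data carry none, so this is only meaningful for
#'   loaded data with a `confounds_<id>.tsv` alongside).
#' @param run_voxelwise Logical; run the TFCE permutation stage.
#' @param n_perm Permutations for the voxel-wise stage.
#' @param local_fdr Mixture-model threshold for the network regions.
#' @param max_auto_order Cap for `"auto"` model-order estimation.
#' @param seed Integer master seed.
#' @param out_dir Optional output directory for TSV/JSON/NIfTI artifacts.
#' @return A `run_config` list.
#' @export
run_config <- function(generator = generator_config(),
                       data_dir = NULL,
                       mo_list = list("auto", 50L, 60L, 70L, 80L, 90L),
                       networks = c("netA", "netB"),
                       control_networks = "netC",
                       methods = c("dual_regression", "template_matching"),
                       template_source = "sample_specific",
                       nuisance_regression = FALSE,
                       run_voxelwise = TRUE,
                       n_perm = 5000L,
                       local_fdr = 0.05,
                       max_auto_order = 30L,
                       seed = 1L,
                       out_dir = NULL) {
  if (length(mo_list) == 0L) stop("`mo_list` must be nonempty", call. = FALSE)
  methods <- match.arg(methods, c("dual_regression", "template_matching"),
                       several.ok = TRUE)
  if (length(methods) == 0L) stop("`methods` must be nonempty", call. = FALSE)
  if (n_perm < 1L) stop("`n_perm` must be positive", call. = FALSE)
  if (local_fdr <= 0 || local_fdr >= 1) stop("`local_fdr` must be in (0,1)", call. = FALSE)
  mo_list <- lapply(mo_list, function(mo) {
    if (identical(mo, "auto")) "auto" else as.integer(mo)
  })
  structure(
    list(generator = generator, data_dir = data_dir, mo_list = mo_list,
         networks = networks, control_networks = control_networks,
         methods = methods, template_source = template_source,
         nuisance_regression = isTRUE(nuisance_regression),
         run_voxelwise = isTRUE(run_voxelwise),
         n_perm = as.integer(n_perm), local_fdr = local_fdr,
         max_auto_order = as.integer(max_auto_order),
         seed = as.integer(seed), out_dir = out_dir),
    class = "run_config"
  )
}

#' Validate a YAML/JSON run configuration file
#'
#' Reads the file, rejects unknown keys with a message naming the offender,
#' checks types and fills defaults. An empty file yields the all-defaults
#' configuration.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` configuration.
#' @return A [run_config()].
#' @export
validate_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("configuration must be a mapping", call. = FALSE)
  gen_keys <- names(formals(generator_config))
  run_keys <- setdiff(names(formals(run_config)), "generator")
  unknown <- setdiff(names(raw), c(run_keys, "generator"))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  gen_args <- raw$generator
  if (!is.null(gen_args)) {
    bad <- setdiff(names(gen_args), gen_keys)
    if (length(bad)) {
      stop("unknown generator key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  gen <- do.call(generator_config, as.list(gen_args))
  do.call(run_config, c(list(generator = gen), raw[setdiff(names(raw), "generator")]))
}

load_cohort <- function(dir) {
  mask <- read_brain_mask(file.path(dir, "mask.nii.gz"))
  phen <- read_phenotypes(file.path(dir, "phenotypes.tsv"))
  series <- lapply(phen$subject_id, function(id) {
    read_bold(file.path(dir, paste0(id, "_bold.nii.gz")), mask,
              subject_id = id)
  })
  names(series) <- phen$subject_id
  tm_files <- list.files(dir, pattern = "^truemap_.*\\.nii\\.gz$",
                         full.names = TRUE)
  maps <- NULL
  if (length(tm_files)) {
    maps <- do.call(rbind, lapply(tm_files, read_map, mask = mask))
    rownames(maps) <- sub("^truemap_(.*)\\.nii\\.gz$", "\\1", basename(tm_files))
  }
  list(series = series, phenotypes = phen, mask = mask, reference_maps = maps)
}

pipeline_references <- function(config, cohort, mask) {
  if (is.list(config$template_source)) {
    maps <- do.call(rbind, lapply(config$template_source, read_map, mask = mask))
    rownames(maps) <- names(config$template_source)
    return(template_set(maps, provenance = "external"))
  }
  all_nets <- c(config$networks, config$control_networks)
  ref_maps <- if (!is.null(cohort$truth)) {
    cohort$truth$true_maps[all_nets, , drop = FALSE]
  } else if (!is.null(cohort$reference_maps)) {
    cohort$reference_maps[all_nets, , drop = FALSE]
  } else {
    stop("no reference maps available for template selection", call. = FALSE)
  }
  template_set(ref_maps, provenance = "sample_specific")
}

#' Run the full network-integrity pipeline
#'
#' Generates (or loads) a cohort, then for every requested model order:
#' temporal-concatenation group ICA, selection of the networks of interest
#' and control networks by spatial correlation with the reference maps,
#' individual-level back-reconstruction by the configured methods,
#' covariate-adjusted group comparison, LOOCV classification, and (optionally)
#' voxel-wise TFCE permutation inference inside the mixture-thresholded
#' network regions. Any cell that fails is recorded with its error message
#' and the remaining cells still run. Fully reproducible from the
#' configuration and its seed.
#'
#' @param config A [run_config()].
#' @return A `run_report` list of tibbles: `records` (integrity),
#'   `comparisons`, `classifications`, `voxelwise`, `selection` (template
#'   matching audit trail: component index and correlation per network/MO),
#'   `failures`, plus `config` and `seed`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cohort <- if (is.null(config$data_dir)) {
    simulate_cohort(config$generator)
  } else {
    load_cohort(config$data_dir)
  }
  mask <- if (!is.null(cohort$truth)) cohort$truth$mask else cohort$mask
  series <- cohort$series
  phen <- cohort$phenotypes

  if (config$nuisance_regression && !is.null(config$data_dir)) {
    series <- lapply(series, function(s) {
      cf <- file.path(config$data_dir, paste0("confounds_", s$subject_id, ".tsv"))
      if (file.exists(cf)) {
        regress_confounds(s, as.matrix(readr::read_tsv(cf, show_col_types = FALSE)))
      } else {
        s
      }
    })
  }

  references <- pipeline_references(config, cohort, mask)
  all_nets <- c(config$networks, config$control_networks)

  concat <- concat_and_normalize(series)
  eigs <- pca_eigs(concat)

  records <- list()
  comparisons <- list()
  classifications <- list()
  voxelwise <- list()
  selection <- list()
  failures <- list()
  note_failure <- function(stage, mo, network, method, e) {
    failures[[length(failures) + 1L]] <<- tibble::tibble(
      stage = stage, MO = as.character(mo),
      network = network %||% NA_character_,
      method = method %||% NA_character_,
      error = conditionMessage(e)
    )
  }

  for (mo in config$mo_list) {
    mo_label <- as.character(mo)
    group_cell <- tryCatch({
      mo_group <- if (identical(mo, "auto")) {
        estimate_model_order(concat, max_order = config$max_auto_order)
      } else {
        mo
      }
      comps <- spatial_ica(concat, mo_group, seed = config$seed, eigs = eigs)
      templates <- select_networks(comps, references)
      sel <- templates$info
      sel$MO <- mo_label
      selection[[mo_label]] <- sel
      list(comps = comps, templates = templates)
    }, error = function(e) {
      note_failure("decomposition", mo_label, NULL, NULL, e)
      NULL
    })
    if (is.null(group_cell)) next

    cell <- list(records = NULL, maps = list(),
                 templates = group_cell$templates)
    for (method in config$methods) {
      ci <- tryCatch(
        cohort_integrity(series, group_cell$comps, group_cell$templates,
                         methods = method, MO = mo, seed = config$seed),
        error = function(e) {
          note_failure("back_reconstruction", mo_label, NULL, method, e)
          NULL
        }
      )
      if (is.null(ci)) next
      cell$records <- dplyr::bind_rows(cell$records, ci$records)
      cell$maps[[method]] <- ci$maps[[method]]
    }
    if (is.null(cell$records)) next
    cell$records$MO <- mo_label
    records[[mo_label]] <- cell$records

    for (method in config$methods) {
      for (net in all_nets) {
        cmp <- tryCatch(
          glance(compare_integrity(cell$records, phen, net, method, MO = mo_label)),
          error = function(e) {
            note_failure("comparison", mo_label, net, method, e)
            NULL
          }
        )
        if (!is.null(cmp)) comparisons[[paste(mo_label, method, net)]] <- cmp
        cls <- tryCatch(
          glance(loocv_logistic_auc(cell$records, phen, net, method, MO = mo_label)),
          error = function(e) {
            note_failure("classification", mo_label, net, method, e)
            NULL
          }
        )
        if (!is.null(cls)) classifications[[paste(mo_label, method, net)]] <- cls

        if (config$run_voxelwise) {
          vw <- tryCatch({
            region <- mixture_threshold(cell$templates$maps[net, ], mask,
                                        local_fdr = config$local_fdr)
            maps_m <- do.call(rbind, lapply(phen$subject_id, function(id) {
              cell$maps[[method]][[id]][net, ]
            }))
            res <- permutation_glm_tfce(maps_m, phen, region, mask,
                                        n_perm = config$n_perm,
                                        seed = config$seed)
            row <- summarize_voxelwise(res)
            row$network <- net
            row$method <- method
            row$MO <- mo_label
            row
          }, error = function(e) {
            note_failure("voxelwise", mo_label, net, method, e)
            NULL
          })
          if (!is.null(vw)) voxelwise[[paste(mo_label, method, net)]] <- vw
        }
      }
    }
  }

  report <- structure(
    list(
      records = dplyr::bind_rows(records),
      comparisons = dplyr::bind_rows(comparisons),
      classifications = dplyr::bind_rows(classifications),
      voxelwise = dplyr::bind_rows(voxelwise),
      selection = dplyr::bind_rows(selection),
      failures = dplyr::bind_rows(failures),
      seed = config$seed,
      config = config
    ),
    class = "run_report"
  )
  if (!is.null(config$out_dir)) write_run_report(report, config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report: %d integrity records, %d comparisons, %d classifications, %d voxelwise rows, %d failures>\n",
              nrow(x$records), nrow(x$comparisons), nrow(x$classifications),
              nrow(x$voxelwise), nrow(x$failures)))
  invisible(x)
}

#' Write a run report to disk
#'
#' TSV tables (integrity records, comparisons, classifications, voxel-wise
#' summaries, template-selection audit) plus a JSON index with the seed.
#'
#' @param report A `run_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(report$records, file.path(dir, "integrity_records.tsv"))
  readr::write_tsv(report$comparisons, file.path(dir, "comparisons.tsv"))
  readr::write_tsv(report$classifications, file.path(dir, "classifications.tsv"))
  readr::write_tsv(report$voxelwise, file.path(dir, "voxelwise.tsv"))
  readr::write_tsv(report$selection, file.path(dir, "selection.tsv"))
  if (nrow(report$failures)) {
    readr::write_tsv(report$failures, file.path(dir, "failures.tsv"))
  }
  jsonlite::write_json(
    list(seed = report$seed,
         n_records = nrow(report$records),
         tables = c("integrity_records.tsv", "comparisons.tsv",
                    "classifications.tsv", "voxelwise.tsv", "selection.tsv")),
    file.path(dir, "report.json"), auto_unbox = TRUE
  )
  invisible(dir)
}

#' Read or write integrity records as TSV
#'
#' The interchange format is
#' `subject_id network method MO r_abs z component low_confidence`.
#'
#' @param records Integrity tibble.
#' @param path TSV path.
#' @return `read_integrity_records()` returns the tibble.
#' @export
write_integrity_records <- function(records, path) {
  readr::write_tsv(records, path)
  invisible(path)
}

#' @rdname write_integrity_records
#' @export
read_integrity_records <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(MO = readr::col_character()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
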