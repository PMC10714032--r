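# End-to-end orchestration: a single config drives the synthetic demo
# and the analysis stages in dependency order, with a JSON manifest
# recording seeds, parameters and output hashes so a run can be
# reproduced exactly.

#' Pipeline configuration
#'
#' Builds the nested configuration consumed by [run_pipeline()]. A single
#' top-level seed is expanded deterministically into per-stage seeds
#' (`seed * 100 + stage index`), so one number reproduces everything.
#'
#' @param seed top-level integer seed (kept small; per-stage seeds must
#'   stay below 2^31).
#' @param out_dir output directory (created if needed); `NULL` disables
#'   file output and returns results in memory only.
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate", "prep", "de", "signatures", "decon", "enrich", "lr",
#'   "ct")`; an empty vector gives a manifest-only run.
#' @param n_genes,n_celltypes,n_markers_per_type,marker_log2fc synthetic
#'   signature settings (see [gen_cell_signatures()]).
#' @param n_samples_per_group cohort size per group.
#' @param noise_sd,dropout_rate proteome noise and missingness settings.
#' @param control_means,case_means named mean cell-type fractions per
#'   group (defaults mirror a neuron-dominated control retina and a
#'   degenerating case retina with expanded glial contribution).
#' @param concentration Dirichlet concentration for sample-to-sample
#'   compositional variation.
#' @param n_de_features,de_log2fc spiked group effects in the proteome.
#' @param p_cut,lfc_cut DE thresholds used by the ligand stage.
#' @param n_perm permutations for enrichment stages.
#' @param inputs optional named list of file paths overriding the
#'   simulated inputs: `intensity` (+`groups`), `cells` (.mtx), `lr`
#'   (TSV), `ct` (CSV). When given, the corresponding simulate output is
#'   ignored.
#' @return list of class `run_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = NULL,
                            stages = c("simulate", "prep", "de", "signatures",
                                       "decon", "enrich", "lr", "ct"),
                            n_genes = 800, n_celltypes = 5,
                            n_markers_per_type = 80, marker_log2fc = 3,
                            n_samples_per_group = 5,
                            noise_sd = 0.1, dropout_rate = 0.1,
                            control_means = c(rod = 0.45, bipolar = 0.23,
                                              amacrine = 0.14, muller = 0.03,
                                              microglia = 0.15),
                            case_means = c(rod = 0.20, bipolar = 0.18,
                                           amacrine = 0.15, muller = 0.22,
                                           microglia = 0.25),
                            concentration = 300,
                            n_de_features = 40, de_log2fc = 1.5,
                            p_cut = 0.05, lfc_cut = 0.5, n_perm = 1000,
                            inputs = list()) {
  all_stages <- c("simulate", "prep", "de", "signatures", "decon", "enrich",
                  "lr", "ct")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop2("unknown stage(s): ", paste(bad, collapse = ", "))
  stopifnot(length(control_means) == n_celltypes,
            length(case_means) == n_celltypes)
  if (abs(seed) * 100 + 10 >= 2^31) stop2("seed too large")
  structure(
    list(seed = as.integer(seed), out_dir = out_dir,
         stages = intersect(all_stages, stages),   # dependency order
         n_genes = n_genes, n_celltypes = n_celltypes,
         n_markers_per_type = n_markers_per_type,
         marker_log2fc = marker_log2fc,
         n_samples_per_group = n_samples_per_group,
         noise_sd = noise_sd, dropout_rate = dropout_rate,
         control_means = control_means, case_means = case_means,
         concentration = concentration,
         n_de_features = n_de_features, de_log2fc = de_log2fc,
         p_cut = p_cut, lfc_cut = lfc_cut, n_perm = n_perm,
         inputs = inputs),
    class = "run_config")
}

# Per-stage seeds derived from the top-level seed.
#' @noRd
stage_seed <- function(cfg, i) cfg$seed * 100L + i

# Fail-fast input validation: every enabled stage must be resolvable
# before execution starts.
#' @noRd
validate_config <- function(cfg) {
  st <- cfg$stages
  needs_sim <- function(file_key) {
    !("simulate" %in% st) && is.null(cfg$inputs[[file_key]])
  }
  if (any(c("prep") %in% st) && needs_sim("intensity")) {
    stop2("stage 'prep' needs stage 'simulate' or an 'intensity' input file")
  }
  if ("signatures" %in% st && needs_sim("cells")) {
    stop2("stage 'signatures' needs stage 'simulate' or a 'cells' input file")
  }
  if ("lr" %in% st && needs_sim("lr")) {
    stop2("stage 'lr' needs stage 'simulate' or an 'lr' input file")
  }
  if ("ct" %in% st && needs_sim("ct")) {
    stop2("stage 'ct' needs stage 'simulate' or a 'ct' input file")
  }
  if ("de" %in% st && !"prep" %in% st) stop2("stage 'de' needs stage 'prep'")
  if ("decon" %in% st && !all(c("prep", "signatures") %in% st)) {
    stop2("stage 'decon' needs stages 'prep' and 'signatures'")
  }
  if ("enrich" %in% st && !all(c("de", "signatures") %in% st)) {
    stop2("stage 'enrich' needs stages 'de' and 'signatures'")
  }
  if ("lr" %in% st && !all(c("de", "signatures") %in% st)) {
    stop2("stage 'lr' needs stages 'de' and 'signatures'")
  }
  for (p in unlist(cfg$inputs)) {
    if (!file.exists(p)) stop2("input file not found: ", p)
  }
  invisible(TRUE)
}

#' Run the pipeline end to end
#'
#' Executes the enabled stages in dependency order (simulate, prep, de,
#' signatures, decon, enrich, lr; ct independently), writes plain-text
#' outputs and a JSON manifest of versions, seeds, parameters and output
#' file hashes, and returns all stage results. Re-running with the same
#' config is bit-identical.
#'
#' @param cfg a [pipeline_config()] (or a YAML file path whose keys match
#'   the `pipeline_config()` arguments; requires the yaml package).
#' @param quiet suppress stage progress messages.
#' @return list of class `ev_run` with one element per executed stage plus
#'   `manifest`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), quiet = FALSE) {
  if (is.character(cfg)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop2("reading a YAML config requires the yaml package")
    }
    cfg <- do.call(pipeline_config, yaml::read_yaml(cfg))
  }
  stopifnot(inherits(cfg, "run_config"))
  validate_config(cfg)
  say <- function(stage, ...) {
    if (!quiet) message(sprintf("[%s] ", stage), ...)
  }
  out_dir <- cfg$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(writer, obj, file) {
    if (is.null(out_dir)) return(NULL)
    writer(obj, file.path(out_dir, file))
    file
  }
  res <- list()
  files <- character(0)
  st <- cfg$stages

  if ("simulate" %in% st) {
    say("simulate", "generating signatures, proteome, cells, Ct array, LR table")
    sigs <- gen_cell_signatures(cfg$n_genes, cfg$n_celltypes,
                                cfg$n_markers_per_type, cfg$marker_log2fc,
                                seed = stage_seed(cfg, 1L),
                                celltype_names = names(cfg$control_means))
    P <- rbind(random_proportions(cfg$n_samples_per_group, cfg$control_means,
                                  cfg$concentration, seed = stage_seed(cfg, 2L)),
               random_proportions(cfg$n_samples_per_group, cfg$case_means,
                                  cfg$concentration, seed = stage_seed(cfg, 3L)))
    rownames(P) <- sprintf("S%02d", seq_len(nrow(P)))
    de_feats <- with_seed(stage_seed(cfg, 4L), {
      f <- sample(rownames(sigs$signature), cfg$n_de_features)
      stats::setNames(rep(c(cfg$de_log2fc, -cfg$de_log2fc),
                          length.out = cfg$n_de_features), f)
    })
    truth <- sim_truth(P, de_features = de_feats,
                       dropout_rate = cfg$dropout_rate,
                       noise_sd = cfg$noise_sd, seed = stage_seed(cfg, 5L))
    proteome <- gen_ev_proteome(sigs, truth)
    cells <- gen_single_cell_counts(sigs, cells_per_type = 40,
                                    seed = stage_seed(cfg, 6L))
    ct <- gen_ct_array(seed = stage_seed(cfg, 7L))
    lr_names <- with_seed(stage_seed(cfg, 9L), {
      ligs <- sample(names(de_feats), 6)
      list(ligands = ligs,
           receptors = sample(setdiff(rownames(sigs$signature),
                                      names(de_feats)), 60))
    })
    lrdb <- gen_lr_database(n_ligands = 6,
                            receptors_per_ligand = c(7, 7, 7, 7, 6, 6),
                            shared_receptor_fraction = 0.2,
                            seed = stage_seed(cfg, 8L),
                            ligand_names = lr_names$ligands,
                            receptor_names = lr_names$receptors)
    res$simulate <- list(signatures = sigs, truth = truth,
                         proteome = proteome, cells = cells, ct = ct,
                         lr = lrdb)
    files <- c(files,
               emit(write_intensity_tsv, proteome, "proteome.tsv"),
               emit(write_cells_mtx, cells, "cells.mtx"),
               emit(write_ct_csv, ct, "ct.csv"),
               emit(write_lr_tsv, lrdb, "lr.tsv"),
               emit(write_sim_truth_json, truth, "truth.json"),
               emit(write_gmt, sigs$markers, "planted_markers.gmt"))
  }

  if ("prep" %in% st) {
    m <- if (!is.null(cfg$inputs$intensity)) {
      read_intensity_tsv(cfg$inputs$intensity, cfg$inputs$groups %||% NULL)
    } else res$simulate$proteome
    say("prep", "filter > impute > vst on ", nrow(m$values), " features")
    filt <- filter_missing(m)
    imp <- impute_minprob(filt, impute_params(filt, seed = stage_seed(cfg, 10L)))
    vst <- vst_normalize(imp)
    res$prep <- list(filtered = filt, imputed = imp, vst = vst)
    files <- c(files, emit(write_intensity_tsv, vst, "prepped.tsv"))
  }

  if ("de" %in% st) {
    say("de", "moderated two-group differential expression")
    de <- de_moderated(res$prep$vst)
    res$de <- de
    if (!is.null(out_dir)) {
      utils::write.table(de, file.path(out_dir, "de.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      files <- c(files, "de.tsv")
    }
  }

  if ("signatures" %in% st) {
    cells <- if (!is.null(cfg$inputs$cells)) read_cells_mtx(cfg$inputs$cells)
             else res$simulate$cells
    say("signatures", "marker derivation and signature matrix from ",
        ncol(cells$counts), " cells")
    markers <- derive_markers(cells, n = cfg$n_markers_per_type)
    sig <- build_signature_matrix(cells, markers)
    res$signatures <- list(markers = markers, signature = sig)
    if (!is.null(out_dir)) {
      files <- c(files, emit(write_gmt, markers, "markers.gmt"))
      utils::write.table(data.frame(gene = rownames(sig), sig,
                                    check.names = FALSE),
                         file.path(out_dir, "signature.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      files <- c(files, "signature.tsv")
    }
  }

  if ("decon" %in% st) {
    say("decon", "cell-type contribution estimation by nu-SVR")
    dc <- deconvolve_cohort(res$prep$imputed, res$signatures$signature)
    res$decon <- dc
    if (!is.null(out_dir)) {
      utils::write.table(data.frame(sample = rownames(dc$proportions),
                                    dc$proportions, check.names = FALSE),
                         file.path(out_dir, "proportions.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(dc$summary, file.path(out_dir, "decon_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      files <- c(files, "proportions.tsv", "decon_summary.tsv")
    }
  }

  if ("enrich" %in% st) {
    say("enrich", "per-cell-type marker-set enrichment")
    grid <- celltype_target_enrichment(res$signatures$markers,
                                       res$signatures$signature,
                                       n_perm = cfg$n_perm,
                                       seed = stage_seed(cfg, 11L))
    hits <- top_table(res$de, p_cut = cfg$p_cut)$feature
    ora <- lapply(res$signatures$markers, function(set) {
      ora_hypergeom(intersect(hits, res$de$feature),
                    intersect(set, res$de$feature), res$de$feature)
    })
    res$enrich <- list(grid = grid,
                       ora = data.frame(set = names(ora),
                                        overlap = vapply(ora, `[[`, numeric(1), "overlap"),
                                        p = vapply(ora, `[[`, numeric(1), "p")))
    if (!is.null(out_dir)) {
      utils::write.table(grid, file.path(out_dir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      files <- c(files, "enrichment.tsv")
    }
  }

  if ("lr" %in% st) {
    lrdb <- if (!is.null(cfg$inputs$lr)) read_lr_tsv(cfg$inputs$lr)
            else res$simulate$lr
    say("lr", "ligand-receptor modules and per-cell-type scoring")
    ligs <- extract_de_ligands(res$de, lrdb, p_cut = cfg$p_cut,
                               lfc_cut = cfg$lfc_cut)
    mapping <- map_receptors(c(ligs$up, ligs$down), lrdb)
    modules <- receptor_modules(ligs, lrdb)
    scores <- tryCatch(
      score_modules(modules, res$signatures$signature, n_perm = cfg$n_perm,
                    seed = stage_seed(cfg, 12L)),
      error = function(e) {
        warning("module scoring skipped: ", conditionMessage(e))
        NULL
      })
    res$lr <- list(ligands = ligs, mapping = mapping, modules = modules,
                   scores = scores)
    if (!is.null(out_dir)) {
      utils::write.table(mapping$interactions,
                         file.path(out_dir, "interactions.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      files <- c(files, "interactions.tsv")
      if (!is.null(scores)) {
        utils::write.table(scores, file.path(out_dir, "module_scores.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        files <- c(files, "module_scores.tsv")
      }
    }
  }

  if ("ct" %in% st) {
    ct <- if (!is.null(cfg$inputs$ct)) read_ct_csv(cfg$inputs$ct)
          else res$simulate$ct
    say("ct", "Ct reliability filtering, normalization, DE")
    filt <- filter_unreliable(ct)
    norm <- normalize_ct(filt, method = "geomean")
    de <- ct_de(norm)
    res$ct <- list(filtered = filt, normalized = norm, de = de)
    if (!is.null(out_dir)) {
      utils::write.table(data.frame(mirna = rownames(norm$ct_matrix$ct),
                                    norm$ct_matrix$ct, check.names = FALSE),
                         file.path(out_dir, "ct_normalized.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(de, file.path(out_dir, "ct_de.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      files <- c(files, "ct_normalized.tsv", "ct_de.tsv")
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("evcargo")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    timestamp = NULL,    # deliberately unset: manifests must be diffable
    seed = cfg$seed,
    stage_seeds = stats::setNames(as.list(cfg$seed * 100L + 1:12),
                                  paste0("slot", 1:12)),
    stages = st,
    parameters = cfg[setdiff(names(cfg), c("out_dir", "inputs"))],
    outputs = if (!is.null(out_dir)) {
      fp <- file.path(out_dir, files)
      stats::setNames(as.list(unname(tools::md5sum(fp))), files)
    } else list())
  res$manifest <- manifest
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  class(res) <- "ev_run"
  invisible(res)
}

#' @export
#' @method print ev_run
print.ev_run <- function(x, ...) {
  cat("ev_run with stages:", paste(setdiff(names(x), "manifest"),
                                   collapse = ", "), "\n")
  invisible(x)
}
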