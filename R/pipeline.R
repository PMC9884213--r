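# End-to-end orchestration of the three phases.  One top-level seed derives
# all module seeds through named streams, so each phase is independently
# reproducible.

#' Pipeline configuration
#'
#' @param seed top-level seed; all module randomness derives from it.
#' @param pitch voxel pitch (mm) for phase-1 similarity metrics.
#' @param n_samples Hausdorff/deviation samples per direction in phase 1.
#' @param phase2_pitch CAD + similarity pitch (mm) for the 120-design phase.
#' @param phase2_samples Hausdorff samples per comparison in phase 2.
#' @param cnn_shape cubic input edge of the classifier (default 32).
#' @param study a [study_config()].
#' @param profiles scanner profile pair ([default_scanner_profiles()]).
#' @param proxy a [proxy_config()].
#' @param train a [train_config()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, pitch = 0.1, n_samples = 50000L,
                            phase2_pitch = 0.2, phase2_samples = 3000L,
                            cnn_shape = 32L, study = study_config(),
                            profiles = default_scanner_profiles(),
                            proxy = proxy_config(),
                            train = train_config()) {
  structure(list(seed = as.integer(seed), pitch = pitch,
                 n_samples = as.integer(n_samples),
                 phase2_pitch = phase2_pitch,
                 phase2_samples = as.integer(phase2_samples),
                 cnn_shape = as.integer(cnn_shape), study = study,
                 profiles = profiles, proxy = proxy, train = train),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the [pipeline_config()] arguments (`seed`, `pitch`,
#' `n_samples`, `phase2_pitch`, `phase2_samples`, `cnn_shape`); nested
#' `study`, `proxy` and `train` blocks override the corresponding
#' sub-configuration fields.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  for (k in intersect(names(y), c("seed", "pitch", "n_samples",
                                  "phase2_pitch", "phase2_samples",
                                  "cnn_shape"))) {
    cfg[[k]] <- if (k %in% c("seed", "n_samples", "phase2_samples",
                             "cnn_shape")) as.integer(y[[k]]) else y[[k]]
  }
  for (blk in c("study", "proxy", "train")) {
    if (!is.null(y[[blk]]))
      cfg[[blk]][names(y[[blk]])] <- y[[blk]]
  }
  cfg
}

pipeline_log <- function(...) {
  message(sprintf("[crownforge] %s", sprintf(...)))
}

#' Phase 1: scanner comparison on the six base preparations
#'
#' Generates the six base prepared teeth, simulates one intraoral and one
#' desktop scan of each, computes a full similarity report per
#' same-specimen pair, and runs pooled t-tests on mesh surface area and
#' enclosed volume between the two scanner groups (two groups of six:
#' df = 10).
#'
#' @param config a [pipeline_config()].
#' @return List: `reports` (6-row data.frame), `t_msa`, `t_vv`
#'   (see [independent_t_test()]), `scans` (list of mesh pairs).
#' @export
run_phase1 <- function(config = pipeline_config()) {
  seed <- config$seed
  sc <- config$study
  reports <- list()
  scans <- list()
  for (b in seq_len(sc$n_base)) {
    tp <- sc$tooth
    tp$seed <- derive_seed(seed, paste0("tooth:", b))
    tp$mesh_pitch <- sc$prep_mesh_pitch
    tooth <- generate_intact_tooth(tp)
    kind <- sc$base_kinds[b]
    spec <- preparation_spec(kind, isthmus_width = sc$isthmus_width,
                             pulpal_depth = sc$pulpal_depth,
                             box_depth = sc$box_depth,
                             divergence_deg = sc$divergence_deg,
                             cusp_reduction = sc$cusp_reduction)
    prep <- if (kind == "inlay") apply_inlay_preparation(tooth, spec)
            else apply_onlay_preparation(tooth, spec)
    io <- simulate_scan(prep, config$profiles$intraoral,
                        seed = derive_seed(seed, paste0("scan-io:", b)))
    dt <- simulate_scan(prep, config$profiles$desktop,
                        seed = derive_seed(seed, paste0("scan-dt:", b)))
    rep <- compare_meshes(io, dt, pitch = config$pitch,
                          n_samples = config$n_samples,
                          seed = derive_seed(seed, paste0("cmp:", b)))
    rep <- cbind(data.frame(specimen = b, kind = kind), rep)
    reports[[b]] <- rep
    scans[[b]] <- list(intraoral = io, desktop = dt)
    pipeline_log("phase1 specimen=%d kind=%s dsc=%.3f hd=%.3f", b, kind,
                 rep$dsc, rep$hd)
  }
  reports <- do.call(rbind, reports)
  list(reports = reports,
       t_msa = independent_t_test(reports$msa_a, reports$msa_b),
       t_vv = independent_t_test(reports$vv_a, reports$vv_b),
       scans = scans)
}

# operator persona: sub-voxel margin placement and smoothing habits
operator_persona <- function(operator, pitch) {
  if (operator == 1L) list(margin_offset = -0.25 * pitch, smooth_iters = 1L)
  else list(margin_offset = 0.25 * pitch, smooth_iters = 2L)
}

#' Phase 2: design the 120 prostheses and analyse them
#'
#' Builds the factorial study (30 preparations), designs each prosthesis
#' under its workflow/operator combination — surface reconstruction for
#' workflow-1 inlays, Boolean subtraction against the intact crown template
#' otherwise — compares every prosthesis with its reference cavity solid,
#' and runs the 2x2x2 factorial ANOVA on MSA, VV, HD and DSC.
#'
#' @param config a [pipeline_config()].
#' @return List: `study` (the design with `prostheses` attached), `reports`
#'   (120-row data.frame), `anova` (named list over msa/vv/hd/dsc), `best`
#'   (per-kind best workflow/operator by mean DSC), `selection` (the 30
#'   selected prosthesis ids for phase 3).
#' @export
run_phase2 <- function(config = pipeline_config()) {
  pitch <- config$phase2_pitch
  study <- build_study_dataset(config$study, seed = config$seed)
  pipeline_log("phase2 built %d preparations, %d design rows",
               length(study$preparations), nrow(study$design))
  cavities <- list()
  for (id in names(study$preparations)) {
    prep <- study$preparations[[id]]
    spec_no <- study$prep_table$specimen[match(id, study$prep_table$prep_id)]
    cavities[[id]] <- preparation_cavity_solid(
      study$teeth[[spec_no]], attr(prep, "preparation_spec"), pitch = pitch)
  }
  design <- study$design
  prostheses <- vector("list", nrow(design))
  rows <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    row <- design[i, ]
    prep <- study$preparations[[row$prep_id]]
    tooth <- study$teeth[[row$specimen]]
    persona <- operator_persona(row$operator, pitch)
    cfg <- cad_config(pitch = pitch,
                      smooth_iters = persona$smooth_iters +
                        (row$workflow == 2L),
                      margin_offset = persona$margin_offset,
                      workflow = row$workflow, operator = row$operator)
    des <- if (row$workflow == 1L && row$kind == "inlay") {
      design_inlay_surface_reconstruction(prep, tooth, cfg)
    } else {
      design_prosthesis_boolean(prep, tooth, row$kind, cfg)
    }
    prostheses[[i]] <- des$prosthesis
    cmp <- compare_meshes(des$prosthesis, cavities[[row$prep_id]],
                          pitch = pitch, n_samples = config$phase2_samples,
                          seed = derive_seed(config$seed, paste0("p2cmp:", i)))
    rows[[i]] <- cbind(row, data.frame(
      msa = cmp$msa_a, vv = cmp$vv_a, hd = cmp$hd, dsc = cmp$dsc,
      signed_dev_min = cmp$signed_dev_min,
      signed_dev_max = cmp$signed_dev_max,
      penetration = des$fit$penetration_volume,
      restored_dice = des$fit$restored_dice), row.names = NULL)
    if (i %% 20 == 0) pipeline_log("phase2 designed %d/%d", i, nrow(design))
  }
  reports <- do.call(rbind, rows)
  anova_tables <- lapply(c(msa = "msa", vv = "vv", hd = "hd", dsc = "dsc"),
                         function(m) three_factor_anova(
                           reports, m, c("kind", "workflow", "operator")))
  # best workflow x operator per kind by mean DSC against the cavity solid
  agg <- aggregate(dsc ~ kind + workflow + operator, reports, mean)
  best <- do.call(rbind, lapply(split(agg, agg$kind), function(g)
    g[which.max(g$dsc), ]))
  sel_idx <- integer(0)
  for (i in seq_len(nrow(reports))) {
    b <- best[best$kind == reports$kind[i], ]
    if (reports$workflow[i] == b$workflow && reports$operator[i] == b$operator)
      sel_idx <- c(sel_idx, i)
  }
  selection <- reports$prep_id[sel_idx]
  study$prostheses <- stats::setNames(prostheses[sel_idx],
                                      reports$prep_id[sel_idx])
  study$prosthesis_kinds <- reports$kind[sel_idx]
  list(study = study, reports = reports, anova = anova_tables, best = best,
       selection = selection, all_prostheses = prostheses)
}

#' Phase 3: train and evaluate the volumetric classifiers
#'
#' Assembles the 30-sample preparation dataset (and, when requested, the
#' 30-sample prosthesis dataset from the best phase-2 workflows), pretrains
#' the feature block on the synthetic proxy task, freezes it, and trains the
#' classification block with early stopping on each dataset.
#'
#' @param config a [pipeline_config()].
#' @param phase2 optional result of [run_phase2()]; required (or computed on
#'   the fly) when `datasets` includes `"prosthesis"`.
#' @param datasets which classifiers to train.
#' @return List: per-dataset `train_result`s plus `pretrain` (proxy history
#'   and accuracy) and `datasets` (the assembled volumes/splits).
#' @export
run_phase3 <- function(config = pipeline_config(), phase2 = NULL,
                       datasets = c("prep", "prosthesis")) {
  datasets <- match.arg(datasets, several.ok = TRUE)
  seed <- config$seed
  if ("prosthesis" %in% datasets && is.null(phase2)) {
    pipeline_log("phase3: no phase-2 result supplied; designing prostheses")
    phase2 <- run_phase2(config)
  }
  study <- if (!is.null(phase2)) phase2$study
           else build_study_dataset(config$study, seed = seed)
  arch <- cnn_architecture(input_shape = rep(config$cnn_shape, 3))
  model <- build_cnn(arch, seed = derive_seed(seed, "cnn"))
  pipeline_log("phase3 pretraining proxy features (%d volumes at %d^3)",
               config$proxy$n_volumes, config$proxy$shape)
  pre <- pretrain_proxy(model, config$proxy, seed = derive_seed(seed, "proxy"))
  pipeline_log("phase3 proxy validation accuracy %.3f", pre$val_acc)
  model <- freeze_feature_block(pre$model)
  out <- list(pretrain = list(val_acc = pre$val_acc, history = pre$history),
              datasets = list())
  for (src in datasets) {
    ds <- assemble_dataset(study, source = src, shape = config$cnn_shape,
                           seed = derive_seed(seed, paste0("split:", src)))
    tc <- config$train
    tc$seed <- derive_seed(seed, paste0("train:", src))
    res <- train_cnn(model, ds$volumes, ds$labels, ds$split, tc)
    pipeline_log("phase3 %s: best val acc %.2f (epoch %d), stop %s at %d",
                 src, res$best_val_acc, res$best_epoch, res$stopping_reason,
                 res$stopped_epoch)
    out$datasets[[src]] <- ds
    out[[src]] <- res
  }
  out
}

#' Run all three phases from one seed
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory for TSV/JSON outputs and a run
#'   manifest.
#' @return List with `phase1`, `phase2`, `phase3` results.
#' @export
run_all_phases <- function(config = pipeline_config(), out_dir = NULL) {
  p1 <- run_phase1(config)
  p2 <- run_phase2(config)
  p3 <- run_phase3(config, phase2 = p2)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(phase1_reports = "phase1_reports.tsv",
               phase2_reports = "phase2_reports.tsv",
               phase3_history_prep = "phase3_history_prep.tsv",
               phase3_history_prosthesis = "phase3_history_prosthesis.tsv")
    write.table(p1$reports, file.path(out_dir, files[1]), sep = "\t",
                row.names = FALSE, quote = FALSE)
    write.table(p2$reports, file.path(out_dir, files[2]), sep = "\t",
                row.names = FALSE, quote = FALSE)
    write.table(p3$prep$history, file.path(out_dir, files[3]), sep = "\t",
                row.names = FALSE, quote = FALSE)
    write.table(p3$prosthesis$history, file.path(out_dir, files[4]),
                sep = "\t", row.names = FALSE, quote = FALSE)
    writeLines(unname(files), file.path(out_dir, "run_manifest.txt"))
  }
  list(phase1 = p1, phase2 = p2, phase3 = p3)
}
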