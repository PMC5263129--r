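#' Simulation configuration for synthetic single-cell qPCR data
#'
#' Describes a synthetic experiment mimicking a 93-gene single-cell RT-qPCR
#' panel profiled across cell-cycle phases (G1, S, G2/M) and two cell sizes,
#' with 12-16 cells per phase-by-size group. Per-cell-per-gene molecule
#' counts are log-normal: a per-gene baseline plus phase and size effects on
#' informative genes, a global per-phase total-transcript shift, a shared
#' per-cell scaling factor (transcriptional bursting makes total transcript
#' levels skewed across cells), and per-entry gene noise. Detection is
#' stochastic with probability logistic in log2 molecules, which produces the
#' dropout pattern seen at sub-detection abundances.
#'
#' @param n_genes number of panel genes.
#' @param groups data.frame with columns `phase` (`"G1"`, `"S"`, `"G2M"`),
#'   `size` (`"small"`, `"large"`) and `n_cells`; defaults to the six
#'   phase-by-size groups of 15-16 cells typical of this design.
#' @param n_informative_phase number of genes carrying a phase effect.
#' @param phase_fold_changes log2 fold change per phase step (G1 -> S -> G2M)
#'   for each informative gene; recycled to `n_informative_phase`.
#' @param n_informative_size number of genes carrying a size effect.
#' @param size_log2_fc log2 fold change (large vs small) for size genes.
#' @param baseline_log2_mean centre of per-gene baselines; baselines are drawn
#'   uniformly in `baseline_log2_mean` +/- 2 (log2 molecules).
#' @param gene_noise_sd per-entry log2 noise SD.
#' @param cell_scale_sd SD (log2) of the shared per-cell scaling factor.
#' @param phase_total_log2 global log2 shift applied to every gene per phase
#'   step, reproducing the rise of total transcript level through the cycle.
#' @param detection_midpoint molecules at which detection probability is 0.5;
#'   `0` disables dropout entirely.
#' @param detection_slope slope of the logistic detection curve in log2
#'   molecule units.
#' @param cq_anchor Cq value corresponding to one molecule.
#' @param cq_cap maximal reportable Cq; larger values are truncated to it.
#' @param subpop optional subpopulation specification from [subpop_spec()].
#' @param line cell-line label written into the annotation.
#' @param seed master seed; all stage seeds derive from it.
#' @return an object of class `sim_config`.
#' @seealso [generate_dataset()], [plant_subpopulation()]
#' @export
sim_config <- function(n_genes = 93,
                       groups = default_groups(),
                       n_informative_phase = 20,
                       phase_fold_changes = 1.5,
                       n_informative_size = 5,
                       size_log2_fc = 1.0,
                       baseline_log2_mean = 5,
                       gene_noise_sd = 0.8,
                       cell_scale_sd = 0.3,
                       phase_total_log2 = 0.5,
                       detection_midpoint = 2,
                       detection_slope = 1.0,
                       cq_anchor = 25,
                       cq_cap = 25,
                       subpop = NULL,
                       line = "LINE1",
                       seed = 1L) {
  n_genes <- as_count(n_genes, "n_genes")
  if (n_genes < 1) abort("n_genes must be positive")
  groups <- as.data.frame(groups)
  stopifnot(all(c("phase", "size", "n_cells") %in% names(groups)))
  if (!all(groups$phase %in% c("G1", "S", "G2M"))) {
    abort("group phases must be in {G1, S, G2M}")
  }
  if (!all(groups$size %in% c("small", "large"))) {
    abort("group sizes must be in {small, large}")
  }
  if (any(groups$n_cells < 1)) abort("every declared group needs >= 1 cell")
  n_informative_phase <- as_count(n_informative_phase, "n_informative_phase")
  n_informative_size <- as_count(n_informative_size, "n_informative_size")
  if (n_informative_phase + n_informative_size > n_genes) {
    abort("more informative genes than panel genes")
  }
  stopifnot(gene_noise_sd >= 0, cell_scale_sd >= 0, detection_midpoint >= 0,
            detection_slope > 0)
  if (!is.null(subpop)) subpop <- validate_subpop_spec(subpop)
  cfg <- list(
    n_genes = n_genes, groups = groups,
    n_informative_phase = n_informative_phase,
    phase_fold_changes = rep_len(phase_fold_changes,
                                 max(n_informative_phase, 1L)),
    n_informative_size = n_informative_size, size_log2_fc = size_log2_fc,
    baseline_log2_mean = baseline_log2_mean, gene_noise_sd = gene_noise_sd,
    cell_scale_sd = cell_scale_sd, phase_total_log2 = phase_total_log2,
    detection_midpoint = detection_midpoint, detection_slope = detection_slope,
    cq_anchor = cq_anchor, cq_cap = cq_cap, subpop = subpop, line = line,
    seed = as.integer(seed)
  )
  structure(cfg, class = "sim_config")
}

#' Default phase-by-size design
#'
#' Six groups (three phases by two sizes) with 15 cells each except 16 in the
#' large-G1 group, matching typical sorted-cell panel sizes.
#' @return data.frame with columns `phase`, `size`, `n_cells`.
#' @export
default_groups <- function() {
  data.frame(
    phase = rep(c("G1", "S", "G2M"), each = 2),
    size = rep(c("small", "large"), 3),
    n_cells = c(15L, 16L, 15L, 15L, 15L, 15L)
  )
}

#' Specify a planted subpopulation
#'
#' A fraction of the cells of one phase receives a global log2 shift on all
#' genes (negative for a low-transcription state) plus an extra shift on one
#' marker gene, emulating a G1 subpopulation with globally reduced
#' transcription but an upregulated marker.
#'
#' @param phase target phase label.
#' @param fraction fraction of target-phase cells turned into members.
#' @param global_shift log2 shift applied to all genes of member cells.
#' @param marker_gene gene id (or 1-based index) of the marker.
#' @param marker_shift additional log2 shift applied to the marker gene on
#'   top of the global shift.
#' @return a `subpop_spec` list.
#' @export
subpop_spec <- function(phase = "G1", fraction = 0.3, global_shift = -1.0,
                        marker_gene = 1L, marker_shift = 1.5) {
  validate_subpop_spec(list(phase = phase, fraction = fraction,
                            global_shift = global_shift,
                            marker_gene = marker_gene,
                            marker_shift = marker_shift))
}

validate_subpop_spec <- function(s) {
  stopifnot(is.list(s), s$phase %in% c("G1", "S", "G2M"),
            s$fraction >= 0, s$fraction <= 1)
  structure(s, class = "subpop_spec")
}

phase_step <- function(phase) {
  unname(c(G1 = 0, S = 1, G2M = 2)[phase])
}

#' Generate a synthetic single-cell qPCR dataset
#'
#' Draws true molecule counts per cell and gene from the log-normal model in
#' [sim_config()], plants an optional subpopulation, applies logistic
#' detection dropout, and reports detected entries as Cq values anchored at
#' `cq_anchor` (Cq = anchor - log2 molecules, truncated at `cq_cap`).
#' Undetected entries are missing (`NA`). The output is reproducible bitwise
#' for a fixed config seed.
#'
#' @param config a [sim_config()] object.
#' @return a list of class `sc_sim` with elements
#'   \describe{
#'     \item{cq}{a [cq_table()] of cells by genes,}
#'     \item{annotation}{data.frame with `cell_id`, `line`, `phase`, `size`,
#'       `treatment`,}
#'     \item{truth}{ground truth: `molecules` (true matrix before dropout),
#'       `phase_genes` and `size_genes` (data.frames of id and direction,
#'       +1 up toward G2M / large, -1 down), `subpop_members` (cell ids),
#'       and the applied config.}
#'   }
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  groups <- cfg$groups
  n_cells <- sum(groups$n_cells)
  gene_ids <- sprintf("g%03d", seq_len(cfg$n_genes))

  ann <- data.frame(
    cell_id = character(0), line = character(0), phase = character(0),
    size = character(0), treatment = character(0)
  )
  for (i in seq_len(nrow(groups))) {
    ids <- sprintf("%s_%s_%s_%02d", cfg$line, groups$phase[i], groups$size[i],
                   seq_len(groups$n_cells[i]))
    ann <- rbind(ann, data.frame(
      cell_id = ids, line = cfg$line, phase = groups$phase[i],
      size = groups$size[i], treatment = "none"
    ))
  }

  # gene-level parameters
  set.seed(derive_seed(cfg$seed, 1L))
  baseline <- stats::runif(cfg$n_genes, cfg$baseline_log2_mean - 2,
                           cfg$baseline_log2_mean + 2)
  informative <- sample.int(cfg$n_genes, cfg$n_informative_phase +
                              cfg$n_informative_size)
  phase_idx <- utils::head(informative, cfg$n_informative_phase)
  size_idx <- utils::tail(informative, cfg$n_informative_size)
  phase_dir <- if (cfg$n_informative_phase > 0) {
    sample(c(-1, 1), cfg$n_informative_phase, replace = TRUE)
  } else numeric(0)
  size_dir <- if (cfg$n_informative_size > 0) {
    sample(c(-1, 1), cfg$n_informative_size, replace = TRUE)
  } else numeric(0)

  # systematic log2 mean per cell-gene
  steps <- phase_step(ann$phase)
  mu <- matrix(rep(baseline, each = n_cells), n_cells, cfg$n_genes)
  if (cfg$n_informative_phase > 0) {
    fc <- cfg$phase_fold_changes
    mu[, phase_idx] <- mu[, phase_idx] +
      outer(steps, phase_dir * fc)
  }
  if (cfg$n_informative_size > 0) {
    mu[, size_idx] <- mu[, size_idx] +
      outer(as.numeric(ann$size == "large"), size_dir * cfg$size_log2_fc)
  }
  mu <- mu + cfg$phase_total_log2 * steps

  set.seed(derive_seed(cfg$seed, 2L))
  cell_scale <- stats::rnorm(n_cells, 0, cfg$cell_scale_sd)
  mu <- mu + cell_scale

  set.seed(derive_seed(cfg$seed, 3L))
  log2_true <- mu + matrix(stats::rnorm(n_cells * cfg$n_genes, 0,
                                        cfg$gene_noise_sd),
                           n_cells, cfg$n_genes)
  molecules <- 2^log2_true
  dimnames(molecules) <- list(ann$cell_id, gene_ids)

  subpop_members <- character(0)
  if (!is.null(cfg$subpop)) {
    planted <- plant_subpopulation(molecules, ann, cfg$subpop,
                                   seed = derive_seed(cfg$seed, 5L))
    molecules <- planted$molecules
    subpop_members <- planted$members
  }

  # logistic detection in log2 molecules; midpoint 0 => always detected
  set.seed(derive_seed(cfg$seed, 4L))
  if (cfg$detection_midpoint > 0) {
    pdet <- stats::plogis(cfg$detection_slope *
                            (log2(molecules) - log2(cfg$detection_midpoint)))
  } else {
    pdet <- matrix(1, n_cells, cfg$n_genes)
  }
  detected <- matrix(stats::runif(n_cells * cfg$n_genes) < pdet,
                     n_cells, cfg$n_genes)

  cq <- cfg$cq_anchor - log2(molecules)
  cq <- pmin(cq, cfg$cq_cap)
  cq[!detected] <- NA_real_
  dimnames(cq) <- dimnames(molecules)

  truth <- list(
    molecules = molecules,
    phase_genes = data.frame(gene = gene_ids[phase_idx],
                             direction = as.integer(phase_dir)),
    size_genes = data.frame(gene = gene_ids[size_idx],
                            direction = as.integer(size_dir)),
    subpop_members = subpop_members,
    config = cfg
  )
  structure(list(cq = cq_table(cq), annotation = ann, truth = truth),
            class = "sc_sim")
}

#' Plant a subpopulation into a true molecule matrix
#'
#' Samples `round(fraction * n)` of the target-phase cells without
#' replacement, multiplies all their genes by `2^global_shift`, and
#' additionally multiplies the marker gene by `2^marker_shift`.
#'
#' @param molecules cells-by-genes matrix of true molecule counts.
#' @param annotation cell annotation with `cell_id` and `phase`.
#' @param spec a [subpop_spec()].
#' @param seed integer seed for member sampling.
#' @return list with the modified `molecules` matrix and the member
#'   `cell_id`s (`members`).
#' @export
plant_subpopulation <- function(molecules, annotation, spec, seed = 1L) {
  spec <- validate_subpop_spec(spec)
  target <- annotation$cell_id[annotation$phase == spec$phase]
  if (length(target) == 0) abort("target phase absent from annotation")
  if (spec$fraction == 0) {
    return(list(molecules = molecules, members = character(0)))
  }
  n_members <- round(spec$fraction * length(target))
  if (n_members == 0) {
    abort("subpopulation fraction yields zero members")
  }
  set.seed(seed)
  members <- sort(sample(target, n_members))
  marker <- spec$marker_gene
  if (is.numeric(marker)) marker <- colnames(molecules)[marker]
  if (!marker %in% colnames(molecules)) abort("marker gene not in matrix")
  molecules[members, ] <- molecules[members, ] * 2^spec$global_shift
  molecules[members, marker] <- molecules[members, marker] * 2^spec$marker_shift
  list(molecules = molecules, members = members)
}

#' Write a simulated dataset as delimited text
#'
#' Emits the Cq matrix, the cell annotation, and a ground-truth sidecar
#' (JSON) into a directory.
#'
#' @param sim an `sc_sim` object from [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "sc_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    cq = file.path(dir, "cq_matrix.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    truth = file.path(dir, "ground_truth.json")
  )
  write_matrix(sim$cq$cq, paths[["cq"]])
  utils::write.table(sim$annotation, paths[["annotation"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  truth$molecules <- NULL  # matrix too large for a sidecar; regenerable
  cfg <- unclass(truth$config)
  cfg$groups <- as.list(cfg$groups)
  if (!is.null(cfg$subpop)) cfg$subpop <- unclass(cfg$subpop)
  truth$config <- cfg
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
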