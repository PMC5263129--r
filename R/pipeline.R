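# End-to-end orchestration: preprocess -> descriptive stats -> pairwise
# classification -> RFE -> subpopulation discovery -> cell-cycle index, with
# a validated configuration serialized (plus its hash) into the output
# bundle for provenance.

pipeline_fields <- c("cq_file", "ann_file", "simulation", "preprocessing",
                     "tasks", "ensemble", "rfe_rule", "clustering",
                     "index_source", "seed")

#' Build and validate a pipeline configuration
#'
#' Inputs are either file paths (`cq_file`, `ann_file`) or a [sim_config()]
#' under `simulation`. Unknown keys are rejected so typos cannot silently
#' disable a stage.
#'
#' @param ... named configuration entries; recognised names:
#'   \describe{
#'     \item{cq_file, ann_file}{delimited input files (alternative to
#'       `simulation`),}
#'     \item{simulation}{a [sim_config()] generating the inputs,}
#'     \item{preprocessing}{list(anchor, cap, efficiency, impute),}
#'     \item{tasks}{list of two-class tasks, each
#'       `list(factor = "phase"|"size", a = <label>, b = <label>)`; default
#'       the three phase pairs plus small vs large,}
#'     \item{ensemble}{list(n_forests, n_trees, pilot_forests, mtry_grid),}
#'     \item{rfe_rule}{signature selection rule, see [optimal_signature()],}
#'     \item{clustering}{list(k, map_length, som_iterations),}
#'     \item{index_source}{`"rfe"` (signature of the first phase task) or a
#'       list(up, down) of gene ids,}
#'     \item{seed}{master seed.}
#'   }
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(...)
  unknown <- setdiff(names(cfg), pipeline_fields)
  if (length(unknown) > 0) {
    abort("unknown configuration field: ", paste(unknown, collapse = ", "))
  }
  defaults <- list(
    preprocessing = list(anchor = 25, cap = 25, efficiency = 1.0,
                         impute = 0.5),
    tasks = list(list(factor = "phase", a = "G1", b = "S"),
                 list(factor = "phase", a = "S", b = "G2M"),
                 list(factor = "phase", a = "G1", b = "G2M"),
                 list(factor = "size", a = "small", b = "large")),
    ensemble = list(n_forests = 100, n_trees = 1000, pilot_forests = 10,
                    mtry_grid = NULL),
    rfe_rule = "one_sd",
    clustering = list(k = 2, map_length = 3, som_iterations = 150),
    index_source = "rfe",
    seed = 1L
  )
  for (f in c("preprocessing", "ensemble", "clustering")) {
    cfg[[f]] <- utils::modifyList(defaults[[f]], as.list(cfg[[f]] %||% list()))
  }
  for (f in c("tasks", "rfe_rule", "index_source", "seed")) {
    cfg[[f]] <- cfg[[f]] %||% defaults[[f]]
  }
  if (is.null(cfg$simulation) && (is.null(cfg$cq_file) || is.null(cfg$ann_file))) {
    abort("provide either 'simulation' or both 'cq_file' and 'ann_file'")
  }
  for (t in cfg$tasks) {
    if (!identical(sort(names(t)), c("a", "b", "factor"))) {
      abort("each task needs fields: factor, a, b")
    }
    valid <- if (t$factor == "phase") c("G1", "S", "G2M")
             else if (t$factor == "size") c("small", "large")
             else abort("task factor must be 'phase' or 'size'")
    bad <- setdiff(c(t$a, t$b), valid)
    if (length(bad) > 0) {
      abort("undefined ", t$factor, " label in task: ", bad[1])
    }
  }
  structure(cfg, class = "pipeline_config")
}

config_json <- function(config) {
  plain <- unclass(config)
  plain$simulation <- if (!is.null(plain$simulation)) {
    s <- unclass(plain$simulation)
    s$groups <- as.list(s$groups)
    if (!is.null(s$subpop)) s$subpop <- unclass(s$subpop)
    s
  }
  jsonlite::toJSON(plain, auto_unbox = TRUE, digits = NA, null = "null")
}

#' Run the full analysis pipeline
#'
#' Executes preprocessing, descriptive statistics, all pairwise
#' classification tasks, recursive feature elimination per task,
#' subpopulation discovery on the G1 cells restricted to the phase
#' signature, and the cell-cycle index, writing every table (tagged with the
#' config hash) into `out_dir`. Deterministic for a fixed config.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory for the report bundle.
#' @param quiet suppress per-stage messages.
#' @return invisibly, a list with all stage results.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(out_dir, "config.json")
  writeLines(config_json(config), cfg_path)
  hash <- unname(tools::md5sum(cfg_path))
  say <- function(stage, t0) {
    if (!quiet) message(sprintf("[%s] done in %.2fs", stage,
                                as.numeric(Sys.time()) - t0))
  }
  emit <- function(df, name) {
    path <- file.path(out_dir, paste0(name, ".tsv"))
    con <- file(path, "w")
    writeLines(paste0("# config_md5 ", hash), con)
    suppressWarnings(
      utils::write.table(df, con, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    )
    close(con)
    path
  }

  # ---- inputs ----
  t0 <- as.numeric(Sys.time())
  if (!is.null(config$simulation)) {
    sim <- generate_dataset(config$simulation)
    cq <- sim$cq
    ann <- sim$annotation
  } else {
    sim <- NULL
    cq <- read_cq_table(config$cq_file)
    ann <- read_annotation(config$ann_file)
  }

  # ---- preprocess ----
  pp <- config$preprocessing
  expr <- cq_to_molecules(cq, anchor = pp$anchor, cap = pp$cap,
                          efficiency = pp$efficiency, impute = pp$impute)
  lx <- log2_matrix(expr)
  say("preprocess", t0)

  # ---- descriptive stats ----
  t0 <- as.numeric(Sys.time())
  totals <- total_transcripts(expr)
  correlations <- do.call(rbind, lapply(
    c("phase", "size", "phase_x_size"),
    function(enc) spearman_vs_factor(totals, ann, enc)
  ))
  census <- pairwise_gene_correlations(lx)
  emit(totals, "totals")
  emit(correlations, "spearman_correlations")
  emit(data.frame(n_pairs = census$n_pairs,
                  fraction_positive = census$fraction_positive,
                  n_excluded = census$n_excluded,
                  range_ratio = range_ratio(totals)),
       "gene_correlation_census")
  say("stats", t0)

  # ---- classification + RFE per task ----
  t0 <- as.numeric(Sys.time())
  ens <- config$ensemble
  tasks <- list()
  for (i in seq_along(config$tasks)) {
    t <- config$tasks[[i]]
    sel <- ann[[t$factor]] %in% c(t$a, t$b)
    cells <- ann$cell_id[sel]
    y <- factor(ann[[t$factor]][sel], levels = c(t$a, t$b))
    genes <- filter_genes_by_detection(expr, ann, split(cells, y))
    X <- lx[cells, genes, drop = FALSE]
    trace <- run_rfe(X, y, n_forests = ens$n_forests, n_trees = ens$n_trees,
                     mtry_grid = ens$mtry_grid,
                     pilot_forests = ens$pilot_forests,
                     seed = derive_seed(config$seed, 11L, i), task_id = i)
    sig <- signature_directions(X, y, optimal_signature(trace,
                                                        config$rfe_rule))
    name <- paste0("task_", t$a, "_vs_", t$b)
    emit(trace$metrics, paste0(name, "_rfe"))
    full <- trace$gene_sets[[1]]
    res1 <- data.frame(
      class_a = t$a, class_b = t$b, n_genes_full = length(full),
      mtry = trace$metrics$mtry[1],
      oob_mean = trace$metrics$oob_mean[1],
      balacc_mean = trace$metrics$balacc_mean[1],
      fisher_p = trace$metrics$fisher_p[1],
      signature = paste(sig$genes, collapse = ","),
      directions = paste(ifelse(sig$directions > 0, "+", "-"), collapse = "")
    )
    emit(res1, paste0(name, "_summary"))
    tasks[[name]] <- list(task = t, trace = trace, signature = sig,
                          cells = cells, y = y)
  }
  say("classify+rfe", t0)

  # ---- subpopulation on G1 cells, phase-signature genes ----
  t0 <- as.numeric(Sys.time())
  phase_tasks <- Filter(function(k) tasks[[k]]$task$factor == "phase",
                        names(tasks))
  sig_genes <- unique(unlist(lapply(phase_tasks,
                                    function(k) tasks[[k]]$signature$genes)))
  g1 <- ann$cell_id[ann$phase == "G1"]
  subpop <- NULL
  if (length(g1) >= 6 && length(sig_genes) >= 2) {
    sx <- suppressWarnings(autoscale(lx[g1, sig_genes, drop = FALSE]))
    scores <- pca_embed(sx, min(2, ncol(sx)))$scores
    cl <- config$clustering
    score <- stats::setNames(totals$total, totals$cell_id)[g1]
    methods <- list(
      pca_gate_clusters(sx, k = cl$k),
      ward_clusters(scores, k = cl$k),
      som_clusters(scores, map_length = cl$map_length,
                   iterations = cl$som_iterations,
                   seed = derive_seed(config$seed, 13L))
    )
    cons <- consensus_subpopulation(methods, score)
    if (length(cons$members) >= 3 &&
        length(setdiff(g1, cons$members)) >= 3) {
      volc <- volcano(lx[g1, , drop = FALSE], cons$members,
                      setdiff(g1, cons$members))
      contrast <- subpop_transcript_contrast(totals, cons$members,
                                             setdiff(g1, cons$members))
      emit(volc, "subpop_volcano")
      emit(data.frame(n_members = length(cons$members),
                      percent_lower = contrast$percent_lower,
                      p_value = contrast$p_value),
           "subpop_contrast")
      subpop <- list(consensus = cons, volcano = volc, contrast = contrast)
    }
    emit(data.frame(cell_id = g1,
                    member = g1 %in% (subpop$consensus$members %||% character(0))),
         "subpop_members")
  }
  say("subpop", t0)

  # ---- cell-cycle index ----
  t0 <- as.numeric(Sys.time())
  if (identical(config$index_source, "rfe")) {
    dirs <- unlist(lapply(phase_tasks, function(k) tasks[[k]]$signature$directions))
    dirs <- dirs[!duplicated(names(dirs))]
    up <- names(dirs)[dirs > 0]
    down <- names(dirs)[dirs < 0]
  } else {
    up <- config$index_source$up
    down <- config$index_source$down %||% character(0)
  }
  idx <- cell_cycle_index(lx, up, down)
  idx$phase <- ann$phase[match(idx$cell_id, ann$cell_id)]
  idx$subpop <- idx$cell_id %in% (subpop$consensus$members %||% character(0))
  xover <- crossover_point(idx, phases = idx$phase)
  emit(idx, "cell_cycle_index")
  emit(data.frame(crossover = xover$crossover, knot_rank = xover$knot_rank,
                  slope_rise = xover$slope_rise,
                  slope_plateau = xover$slope_plateau,
                  distinct = xover$distinct),
       "index_crossover")
  say("index", t0)

  invisible(list(expr = expr, totals = totals, correlations = correlations,
                 census = census, tasks = tasks, subpop = subpop,
                 index = idx, crossover = xover, config_hash = hash,
                 sim = sim))
}
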