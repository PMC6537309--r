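# End-to-end driver: config in, run directory of tables + manifest out.

#' Build a run configuration
#'
#' Validates and normalizes the settings consumed by [run_pipeline()].
#' Two analysis modes exist: `"two_condition"` uses the sample sheet's
#' condition labels directly; `"group_by_driver_gene"` first splits the
#' cohort into the `k` highest- and `k` lowest-expressing samples of
#' `driver_gene` (requires an expression matrix) and then runs the
#' two-condition path on those groups, with the low group as condition a.
#'
#' @param annotation Path to a GTF annotation, or a `simulate` list (see
#'   below) instead.
#' @param sample_sheet data.frame (or TSV path) with columns
#'   `sample_id`, `condition`, and — unless simulating — `junctions`
#'   (per-sample BED12 junction file paths).
#' @param out_dir Output directory, created if missing.
#' @param mode `"two_condition"` or `"group_by_driver_gene"`.
#' @param driver_gene,k Driver gene id and group size for
#'   `group_by_driver_gene` mode.
#' @param expression Optional genes x samples FPKM matrix (or TSV path);
#'   enables correlation/DEG outputs and driver-gene grouping.
#' @param gene_sets Optional GMT path for enrichment of RASE genes.
#' @param simulate Optional list of synthetic-bundle settings
#'   (`event_mix`, `n_regulated`, `effect_size`, `depth_per_event`,
#'   `n_samples_per_condition`, `dispersion`); replaces annotation and
#'   junction files.
#' @param p_threshold,ratio_threshold RASE calling thresholds.
#' @param fc_up,fc_down,alpha,use_fdr DEG filter settings.
#' @param min_novel_reads Novel-junction read support (see
#'   [discover_novel_events()]).
#' @param concordance Optional list(`run_dir`, `invert_a`, `invert_b`):
#'   compare directions against a previous run directory.
#' @param seed Integer seed for all randomness in the run.
#' @return A validated `run_config` list.
#' @export
run_config <- function(annotation = NULL, sample_sheet = NULL, out_dir,
                       mode = c("two_condition", "group_by_driver_gene"),
                       driver_gene = NULL, k = NULL, expression = NULL,
                       gene_sets = NULL, simulate = NULL,
                       p_threshold = 0.05, ratio_threshold = 0.2,
                       fc_up = 2, fc_down = 0.5, alpha = 0.05,
                       use_fdr = TRUE, min_novel_reads = 2L,
                       concordance = NULL, seed = 1L) {
  mode <- match.arg(mode)
  if (p_threshold <= 0 || p_threshold > 1) stop("p_threshold must be in (0, 1]")
  if (ratio_threshold < 0 || ratio_threshold >= 1) {
    stop("ratio_threshold must be in [0, 1)")
  }
  if (fc_up <= 1 || fc_down >= 1 || fc_down <= 0) {
    stop("require fc_up > 1 and 0 < fc_down < 1")
  }
  if (mode == "group_by_driver_gene") {
    if (is.null(driver_gene) || is.null(k)) {
      stop("group_by_driver_gene mode needs driver_gene and k")
    }
    if (is.null(expression) && is.null(simulate)) {
      stop("group_by_driver_gene mode needs an expression matrix")
    }
  }
  if (is.null(simulate) && is.null(annotation)) {
    stop("either an annotation or a simulate block is required")
  }
  structure(list(annotation = annotation, sample_sheet = sample_sheet,
                 out_dir = out_dir, mode = mode, driver_gene = driver_gene,
                 k = k, expression = expression, gene_sets = gene_sets,
                 simulate = simulate, p_threshold = p_threshold,
                 ratio_threshold = ratio_threshold, fc_up = fc_up,
                 fc_down = fc_down, alpha = alpha, use_fdr = use_fdr,
                 min_novel_reads = as.integer(min_novel_reads),
                 concordance = concordance, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys mirror the [run_config()] arguments.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$simulate$event_mix)) {
    raw$simulate$event_mix <- unlist(raw$simulate$event_mix)
  }
  do.call(run_config, raw)
}

#' Run the full splicing analysis pipeline
#'
#' Executes annotation parsing (or synthetic-bundle generation), event
#' enumeration, novel-event discovery, per-condition pooling, RASE
#' calling, per-type tallies, and — when inputs allow — expression
#' summaries (correlation matrix, DEG filter), enrichment of RASE genes
#' and cross-run concordance. All tables land in `config$out_dir`; a
#' `manifest.json` records the configuration, package version and
#' per-stage counts. Identical config and inputs give byte-identical
#' outputs; on failure, partial outputs are removed.
#'
#' @param config A [run_config()] object.
#' @return Invisibly, a list with the main in-memory results
#'   (`events`, `event_counts`, `rases`, `type_counts`, paths, ...).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)
  emit <- function(obj, name, writer = write_tsv_plain) {
    path <- file.path(out_dir, name)
    writer(obj, path)
    written <<- c(written, path)
    path
  }
  log_counts <- list()

  ## ---- inputs ---------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim <- resolve_simulation(config)
    graphs <- sim$graphs
    evidence <- sim$evidence
    sheet <- sim$sample_sheet
    expr <- sim$expr
    emit(sim$annotation$truth, "truth_events.tsv", write_event_table)
    emit(sim$splicing_truth, "truth_splicing.tsv")
  } else {
    graphs <- parse_annotation(config$annotation)
    sheet <- config$sample_sheet
    if (is.character(sheet)) sheet <- read.delim(sheet, stringsAsFactors = FALSE)
    if (is.null(sheet) || !all(c("sample_id", "condition") %in% names(sheet))) {
      stop("sample sheet with sample_id and condition columns is required")
    }
    if (!"junctions" %in% names(sheet)) {
      stop("sample sheet must name a junction BED file per sample")
    }
    missing <- sheet$junctions[!file.exists(sheet$junctions)]
    if (length(missing)) stop("missing junction file: ", missing[1L])
    evidence <- lapply(seq_len(nrow(sheet)), function(i) {
      read_junction_bed(sheet$junctions[i], sheet$sample_id[i])
    })
    names(evidence) <- sheet$sample_id
    expr <- config$expression
    if (is.character(expr)) {
      expr <- as.matrix(read.delim(expr, row.names = 1L, check.names = FALSE))
    }
  }

  ## ---- grouping -------------------------------------------------------
  if (config$mode == "group_by_driver_gene") {
    if (is.null(expr) || !config$driver_gene %in% rownames(expr)) {
      stop("driver gene ", config$driver_gene, " not in expression matrix")
    }
    grp <- select_extreme_groups(expr[config$driver_gene, ], config$k)
    sheet <- data.frame(sample_id = c(grp$low, grp$high),
                        condition = rep(c("low", "high"), each = config$k),
                        stringsAsFactors = FALSE)
    evidence <- evidence[sheet$sample_id]
    cond_a <- "low"; cond_b <- "high"
  } else {
    conds <- unique(sheet$condition)
    if (length(conds) != 2L) stop("two_condition mode needs exactly 2 conditions")
    cond_a <- conds[1L]; cond_b <- conds[2L]
    if (any(table(sheet$condition) < 2L)) {
      warning("a condition has a single sample: no biological replication")
    }
  }
  log_counts$samples <- nrow(sheet)

  ## ---- events ---------------------------------------------------------
  known <- enumerate_all_known_events(graphs)
  pooled_counts <- Reduce(function(x, y) {
    merged <- x
    common <- union(names(x$counts), names(y$counts))
    cc <- setNames(integer(length(common)), common)
    cc[names(x$counts)] <- cc[names(x$counts)] + x$counts
    cc[names(y$counts)] <- cc[names(y$counts)] + y$counts
    merged$counts <- cc
    merged
  }, evidence)
  novel <- do.call(rbind, c(lapply(graphs, discover_novel_events,
                                   evidence = pooled_counts,
                                   min_reads = config$min_novel_reads),
                            list(empty_event_table())))
  rownames(novel) <- NULL
  events <- rbind(known, novel)
  log_counts$known_events <- nrow(known)
  log_counts$novel_events <- nrow(novel)
  emit(events, "events.tsv", write_event_table)

  ## ---- differential splicing -----------------------------------------
  ec <- pool_condition(events, evidence, sheet, cond_a, cond_b)
  emit(ec, "event_counts.tsv")
  rases <- call_rases(ec, config$p_threshold, config$ratio_threshold)
  emit(rases, "rases.tsv",
       function(obj, path) write_rase_table(obj, path, events = events))
  log_counts$events_testable <- sum(rases$testable)
  log_counts$rases_called <- sum(rases$is_rase)
  type_counts <- classify_rase_types(rases, events)
  emit(type_counts, "rase_type_counts.tsv")
  qc <- data.frame(
    sample_id = vapply(evidence, `[[`, character(1), "sample_id"),
    junction_reads = vapply(evidence, function(e) sum(e$counts), numeric(1)),
    mapped_fragments = vapply(evidence, `[[`, numeric(1),
                              "total_mapped_fragments"),
    junction_read_fraction = vapply(evidence, junction_read_fraction,
                                    numeric(1)))
  emit(qc, "sample_qc.tsv")

  ## ---- expression -----------------------------------------------------
  degs <- NULL
  if (!is.null(expr)) {
    cm <- pearson_correlation_matrix(expr)
    emit(as.data.frame(cm), "correlation.tsv",
         function(obj, path) write.table(obj, path, sep = "\t", quote = FALSE))
    ga <- sheet$sample_id[sheet$condition == cond_a]
    gb <- sheet$sample_id[sheet$condition == cond_b]
    ga <- intersect(ga, colnames(expr)); gb <- intersect(gb, colnames(expr))
    if (length(ga) && length(gb)) {
      fc <- fold_changes(expr, ga, gb)
      # FPKM-scale pseudo-counts: the binomial engine needs integers
      pa <- setNames(round(rowSums(expr[, ga, drop = FALSE])), rownames(expr))
      pb <- setNames(round(rowSums(expr[, gb, drop = FALSE])), rownames(expr))
      pv <- binomial_deg_test(pa, pb)
      fc$p_value <- pv$p_value[match(fc$gene_id, pv$gene_id)]
      degs <- deg_filter(fc, config$fc_up, config$fc_down, config$use_fdr,
                         config$alpha)
      emit(degs, "degs.tsv")
      log_counts$degs_up <- unname(attr(degs, "n_updown")["up"])
      log_counts$degs_down <- unname(attr(degs, "n_updown")["down"])
    }
  }

  ## ---- enrichment -----------------------------------------------------
  enr <- NULL
  if (!is.null(config$gene_sets)) {
    sets <- read_gmt(config$gene_sets)
    universe <- unique(events$gene_id)
    query <- unique(events$gene_id[match(rases$event_id[rases$is_rase],
                                         events$event_id)])
    if (length(query)) {
      enr <- hypergeometric_enrichment(query, sets, universe)
      emit(enr, "enrichment.tsv")
    }
  }

  ## ---- concordance ----------------------------------------------------
  conc <- NULL
  if (!is.null(config$concordance)) {
    other <- config$concordance$run_dir
    other_rases <- read.delim(file.path(other, "rases.tsv"),
                              stringsAsFactors = FALSE)
    other_events <- read_event_table(file.path(other, "events.tsv"))
    conc <- compare_directions(
      rases, other_rases, events, other_events,
      invert_a = isTRUE(config$concordance$invert_a),
      invert_b = isTRUE(config$concordance$invert_b))
    emit(conc$records, "concordance.tsv")
    log_counts$concordant_same <- conc$n_same
    log_counts$concordant_opposite <- conc$n_opposite
  }

  ## ---- manifest -------------------------------------------------------
  manifest <- list(
    package = "rasekit",
    version = as.character(utils::packageVersion("rasekit")),
    seed = config$seed,
    mode = config$mode,
    conditions = list(a = cond_a, b = cond_b),
    thresholds = list(p = config$p_threshold, rase_ratio = config$ratio_threshold,
                      fc_up = config$fc_up, fc_down = config$fc_down,
                      alpha = config$alpha),
    counts = log_counts)
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  written <- c(written, manifest_path)
  ok <- TRUE
  invisible(list(events = events, event_counts = ec, rases = rases,
                 type_counts = type_counts, degs = degs, enrichment = enr,
                 concordance = conc, out_dir = out_dir, manifest = manifest))
}

resolve_simulation <- function(config) {
  sim <- config$simulate
  mix <- sim$event_mix
  if (is.null(mix)) mix <- setNames(rep(1L, length(EVENT_TYPES)), EVENT_TYPES)
  ann <- make_toy_annotation(mix, seed = config$seed)
  n_reg <- if (is.null(sim$n_regulated)) {
    ceiling(nrow(ann$truth) / 3)
  } else sim$n_regulated
  truth <- make_splicing_truth(
    ann$truth$event_id, n_regulated = n_reg,
    effect_size = if (is.null(sim$effect_size)) 0.3 else sim$effect_size,
    seed = config$seed)
  jc <- simulate_junction_counts(
    ann, truth,
    depth_per_event = if (is.null(sim$depth_per_event)) 100L else sim$depth_per_event,
    n_samples_per_condition = if (is.null(sim$n_samples_per_condition)) 2L
      else sim$n_samples_per_condition,
    dispersion = if (is.null(sim$dispersion)) 0 else sim$dispersion,
    seed = config$seed)
  etruth <- make_expression_truth(
    names(ann$graphs),
    n_deg = max(1L, length(ann$graphs) %/% 4L),
    seed = config$seed)
  ex <- simulate_expression(
    etruth,
    n_samples_per_condition = table(jc$sample_sheet$condition)[c("a", "b")],
    seed = config$seed)
  list(graphs = ann$graphs, annotation = ann, splicing_truth = truth,
       evidence = jc$evidence, sample_sheet = jc$sample_sheet,
       expr = ex$expr)
}

write_tsv_plain <- function(obj, path) {
  write.table(obj, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
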