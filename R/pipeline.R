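#' Default pipeline configuration
#'
#' Returns the full configuration list for [run_pipeline()] with documented
#' defaults; override fields by name. Paths are NULL until set. Thresholds:
#' \code{min_codons} 30 (CDS QC), \code{r_min} 0.5 and \code{p_max} 0.05
#' (screen selection), \code{alpha} 0.05 and \code{lfc_min} 1 (DEG calls),
#' \code{c} 2 and \code{m} 50 (model profiles), \code{baseline} "Control".
#'
#' @param ... Named overrides.
#' @return Named list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    query_fasta = NULL, host_fasta = NULL,
    counts = NULL, group_map = NULL,
    deg_tables = NULL,       # list: contrast -> c(path_a, path_b)
    ct_table = NULL, ct_target = "target", ct_reference = "GAPDH",
    min_codons = 30L, r_min = 0.5, p_max = 0.05,
    alpha = 0.05, lfc_min = 1, c = 2L, m = 50L,
    baseline = "Control", group_order = NULL,
    stages = c("indices", "adapt", "screen", "expression"),
    outdir = "cubscreen_run", seed = 1L
  )
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1L]]) && is.null(names(over))) {
    over <- over[[1L]]
  }
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0L) stop("unknown config field(s): ",
                             paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Run the full codon-usage / expression-response pipeline
#'
#' Executes, in order, the stages enabled in the configuration:
#' \describe{
#'   \item{indices}{read + QC both FASTA files; per-gene index tables
#'     (GC, ENC, SCUO, PR2) and distribution summaries for both organisms.}
#'   \item{adapt}{host-adaptation indices of the query organism against the
#'     host: per-gene CAI and RCDI (added to the query index table) and the
#'     organism-level SiD on genome RSCU.}
#'   \item{screen}{per-gene RSCU matrix of the query vs the host
#'     organism-level RSCU profile; selection at r >= r_min, p < p_max.}
#'   \item{expression}{subset the count matrix to screen-selected genes,
#'     merge each contrast's two DEG tables, fit model profiles with exact
#'     permutation significance, and (if a Ct table is given) compute
#'     2^-ddCt fold changes.}
#' }
#' All stage outputs are written as TSV under \code{config$outdir}, plus a
#' \code{manifest.json} recording the package version, seed, input
#' checksums, per-stage record counts and output checksums. Outputs are a
#' pure function of (inputs, config, seed).
#'
#' @param config List from [pipeline_config()], or a path to a YAML file of
#'   overrides.
#' @return The manifest, invisibly (a list).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- pipeline_config(yaml::read_yaml(config))
  }
  cfg <- pipeline_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(as.integer(cfg$seed))
  manifest <- list(package = "cubscreen",
                   version = as.character(utils::packageVersion("cubscreen")),
                   seed = cfg$seed, stages = list(), inputs = list())
  note_input <- function(field) {
    p <- cfg[[field]]
    if (is.character(p) && length(p) == 1L && file.exists(p)) {
      manifest$inputs[[field]] <<- unname(tools::md5sum(p))
    }
  }
  for (f in c("query_fasta", "host_fasta", "counts", "group_map",
              "ct_table")) note_input(f)

  outputs <- character(0)
  emit <- function(df, name) {
    p <- file.path(cfg$outdir, name)
    write_tsv_table(df, p)
    outputs <<- c(outputs, p)
    p
  }
  stage_fail <- function(stage, e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }

  query <- host <- NULL
  query_counts <- host_counts <- NULL
  screen_tab <- NULL

  if ("indices" %in% cfg$stages || "adapt" %in% cfg$stages ||
      "screen" %in% cfg$stages) {
    tryCatch({
      if (is.null(cfg$query_fasta) || is.null(cfg$host_fasta)) {
        stop("config fields 'query_fasta' and 'host_fasta' are required")
      }
      query <- read_and_qc(cfg$query_fasta, min_codons = cfg$min_codons)
      host <- read_and_qc(cfg$host_fasta, min_codons = cfg$min_codons)
      query_counts <- count_codons(query)
      host_counts <- count_codons(host)
    }, error = function(e) stage_fail("input", e))
  }

  if ("indices" %in% cfg$stages) {
    tryCatch({
      hc <- if ("adapt" %in% cfg$stages) colSums(host_counts) else NULL
      qi <- gene_indices(query, host_counts = hc)
      hi <- gene_indices(host)
      emit(query$qc, "query_qc.tsv")
      emit(host$qc, "host_qc.tsv")
      emit(qi, "query_indices.tsv")
      emit(hi, "host_indices.tsv")
      emit(index_summary_and_correlations(qi)$summary,
           "query_index_summary.tsv")
      manifest$stages$indices <- list(n_query = nrow(qi), n_host = nrow(hi))
    }, error = function(e) stage_fail("indices", e))
  }

  if ("adapt" %in% cfg$stages) {
    tryCatch({
      sid_rscu <- sid(organism_rscu(query_counts), organism_rscu(host_counts))
      adapt <- data.frame(metric = "sid_rscu", value = sid_rscu)
      emit(adapt, "adaptation.tsv")
      manifest$stages$adapt <- list(sid_rscu = sid_rscu)
    }, error = function(e) stage_fail("adapt", e))
  }

  if ("screen" %in% cfg$stages) {
    tryCatch({
      qm <- build_rscu_matrix(query_counts)
      prof <- organism_rscu(host_counts)
      screen_tab <- screen_genes(qm, prof, mode = "profile",
                                 r_min = cfg$r_min, p_max = cfg$p_max)
      emit(screen_tab, "screen.tsv")
      manifest$stages$screen <- list(n_tested = sum(screen_tab$testable),
                                      n_selected = sum(screen_tab$selected))
    }, error = function(e) stage_fail("screen", e))
  }

  if ("expression" %in% cfg$stages) {
    tryCatch({
      if (is.null(cfg$counts) || is.null(cfg$group_map)) {
        stop("config fields 'counts' and 'group_map' are required for the ",
             "expression stage")
      }
      cm <- as.matrix(utils::read.table(cfg$counts, header = TRUE,
                                        sep = "\t", row.names = 1L,
                                        check.names = FALSE))
      gm <- utils::read.table(cfg$group_map, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
      groups <- gm$group[match(colnames(cm), gm$sample)]
      if (anyNA(groups)) stop("group map does not cover all samples")
      group_order <- cfg$group_order
      if (is.null(group_order)) group_order <- unique(groups)
      if (!is.null(screen_tab)) {
        keep <- intersect(rownames(cm),
                          screen_tab$gene_id[screen_tab$selected])
        if (length(keep) > 0L) cm <- cm[keep, , drop = FALSE]
      }
      n_merged <- list()
      if (!is.null(cfg$deg_tables)) {
        for (contrast in names(cfg$deg_tables)) {
          paths <- cfg$deg_tables[[contrast]]
          rd <- function(p) utils::read.table(p, header = TRUE, sep = "\t",
                                              stringsAsFactors = FALSE)
          mg <- merge_degs(call_degs(rd(paths[[1L]]), cfg$alpha, cfg$lfc_min),
                           call_degs(rd(paths[[2L]]), cfg$alpha, cfg$lfc_min))
          mdf <- data.frame(
            gene_id = c(mg$common_up, mg$common_down),
            direction = rep(c("up", "down"), c(mg$n_up, mg$n_down)))
          emit(mdf, paste0("merged_degs_", contrast, ".tsv"))
          n_merged[[contrast]] <- c(up = mg$n_up, down = mg$n_down)
        }
      }
      profs <- stem_profiles(length(group_order), cfg$c, cfg$m)
      fit <- assign_and_test_profiles(cm, groups, profs,
                                      group_order = group_order,
                                      baseline = cfg$baseline,
                                      alpha = cfg$alpha)
      emit(fit$table, "profiles.tsv")
      emit(data.frame(gene_id = names(fit$assignments),
                      profile_id = unname(fit$assignments)),
           "profile_assignments.tsv")
      manifest$stages$expression <- list(
        n_genes = nrow(cm), merged = n_merged,
        n_significant_profiles = sum(fit$table$significant))
      if (!is.null(cfg$ct_table)) {
        ctab <- utils::read.table(cfg$ct_table, header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE)
        dd <- ddct_fold_change(ctab, cfg$ct_target, cfg$ct_reference,
                               cfg$baseline)
        emit(dd, "ddct.tsv")
        manifest$stages$expression$n_ddct_samples <- nrow(dd)
      }
    }, error = function(e) stage_fail("expression", e))
  }

  manifest$outputs <- lapply(stats::setNames(outputs, basename(outputs)),
                             function(p) unname(tools::md5sum(p)))
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Write a complete set of synthetic pipeline inputs
#'
#' Generates, under one directory, everything [run_pipeline()] consumes:
#' query and host CDS FASTA files (with planted host-similar query genes),
#' a count matrix TSV and sample-group map (with planted profile genes
#' among the planted-similar ids), fabricated DEG table pairs per contrast,
#' a Ct table, and a \code{truth.json} recording all planted structure.
#'
#' @param outdir Output directory (created).
#' @param seed Integer master seed; stage seeds are derived from it.
#' @param n_genes Genes per organism (default 2000).
#' @param n_planted Planted host-similar query genes (default 200).
#' @param lambda Mixing weight of planted genes (default 0.9).
#' @param n_profile Planted rescue-profile genes (default 200), drawn from
#'   the planted-similar ids.
#' @param effect Planted profile effect size in log2 units (default 2).
#' @param dispersion NB dispersion (default 0.1).
#' @return Named list of file paths plus the truth list, invisibly.
#' @export
simulate_inputs <- function(outdir, seed = 1L, n_genes = 2000L,
                            n_planted = 200L, lambda = 0.9,
                            n_profile = 200L, effect = 2,
                            dispersion = 0.1) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  query_model <- codon_model(seed, gc3_bias = 0.38)
  host_model <- codon_model(seed + 1L, gc3_bias = 0.58)
  query <- generate_cds_set(query_model, n_genes = n_genes,
                            partner_model = host_model,
                            n_planted = n_planted, lambda = lambda,
                            seed = seed + 2L, id_prefix = "q")
  host <- generate_cds_set(host_model, n_genes = n_genes,
                           seed = seed + 3L, id_prefix = "h")
  paths <- list(
    query_fasta = file.path(outdir, "query_cds.fasta"),
    host_fasta = file.path(outdir, "host_cds.fasta"),
    counts = file.path(outdir, "counts.tsv"),
    group_map = file.path(outdir, "group_map.tsv"),
    ct_table = file.path(outdir, "ct.tsv")
  )
  write_cds_fasta(query, paths$query_fasta)
  write_cds_fasta(host, paths$host_fasta)

  sim <- simulate_counts(
    n_genes = n_genes,
    planted_profiles = list(list(pattern = c(0, 0, 1, 0), n = n_profile,
                                 effect = effect)),
    dispersion = dispersion, seed = seed + 4L)
  # align count-matrix gene ids with the query FASTA ids so that planted
  # rescue-profile genes fall inside the planted-similar set
  rownames(sim$counts) <- names(query$sequences)
  write_tsv_table(sim$counts, paths$counts)
  utils::write.table(
    data.frame(sample = colnames(sim$counts), group = sim$groups),
    paths$group_map, sep = "\t", quote = FALSE, row.names = FALSE)

  deg_paths <- list()
  for (contrast in names(sim$deg_tables)) {
    pa <- file.path(outdir, paste0("deg_", contrast, "_a.tsv"))
    pb <- file.path(outdir, paste0("deg_", contrast, "_b.tsv"))
    ta <- sim$deg_tables[[contrast]]$genewise_t
    tb <- sim$deg_tables[[contrast]]$global_z
    ta$gene_id <- rownames(sim$counts)
    tb$gene_id <- rownames(sim$counts)
    write_tsv_table(ta, pa)
    write_tsv_table(tb, pb)
    deg_paths[[contrast]] <- c(pa, pb)
  }
  ctsim <- simulate_ct_table(
    c(Control = 1, Bacterium = 1, Calcium = 4, CalciumBacterium = 1),
    seed = seed + 5L)
  write_tsv_table(ctsim$ct, paths$ct_table)

  truth <- list(
    planted_similar_gene_ids = query$truth$planted_similar_gene_ids,
    lambda = lambda,
    planted_profile_gene_ids = lapply(sim$truth$planted_profile_gene_ids,
      function(ids) rownames(sim$counts)[match(ids, sprintf("g%05d",
        seq_len(n_genes)))]),
    ct_truth = ctsim$truth$fold_by_group,
    seed = seed)
  jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths$deg_tables <- deg_paths
  paths$truth <- truth
  invisible(paths)
}
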