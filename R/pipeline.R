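# Config-driven orchestration of the whole analysis, mirroring the order
# of the study it emulates: two-group DE on counts -> overlap with a focus
# gene set and z-score composite -> time-course profile clustering ->
# term enrichment -> GSEA -> co-expression network and hub report.
# Every stochastic stage gets its own seed derived from the single global
# seed, so one integer reproduces the entire run.

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file path.
#' @return a config list (see [default_pipeline_config()] for the shape).
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  utils::modifyList(default_pipeline_config(), cfg)
}

#' Default pipeline configuration
#'
#' The default runs fully synthetic: the simulate stage generates a
#' two-group count matrix with planted DEGs, a 4-time-point log2 course
#' with genes planted into model profiles, and a co-expression matrix with
#' a planted hub; the focus gene set (standing in for a curated
#' lysosomal/autophagic list) is the planted DEG set. DE gates default to
#' the human RNA-seq criteria (FC > 1.2 or < 0.833, FDR < 0.2).
#'
#' @return a nested list of stage parameters.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    output_dir = "lysoflux_run",
    precision = 6L,
    stages = list(simulate = TRUE, diffexp = TRUE, overlap = TRUE,
                  zscore = TRUE, profiles = TRUE, enrichment = TRUE,
                  gsea = TRUE, network = TRUE),
    inputs = list(),
    simulate = list(
      counts = list(n_genes = 1000L, samples_per_group = 10L,
                    baseline_mean = 100, dispersion = 0.1,
                    n_planted = 60L, planted_log2fc = 2),
      timecourse = list(n_genes = 300L, n_planted = 120L, noise_sd = 0.25,
                        replicates = 3L, step_size = 1),
      coexpression = list(n_genes = 322L, n_samples = 100L, module_size = 12L,
                          loading_hub = 0.95, loading_member = 0.6)
    ),
    diffexp = list(fc_up = 1.2, fc_down = 0.833, alpha = 0.2,
                   alpha_kind = "fdr"),
    profiles = list(c = 1L, step_size = 1.0, n_permutations = 100L),
    enrichment = list(n_terms = 20L, term_size = 25L),
    gsea = list(n_permutations = 200L, weight_p = 1,
                metric = "signal_to_noise", n_random_sets = 10L,
                set_size = 25L),
    network = list(fdr_max = 0.05, r_min = NULL)
  )
}

pipeline_need <- function(state, what, stage) {
  if (is.null(state[[what]])) {
    stop(sprintf("stage '%s' output required but stage is disabled and no file was supplied",
                 stage), call. = FALSE)
  }
  state[[what]]
}

#' Run the full pipeline
#'
#' Stages execute in dependency order; each stage writes its result tables
#' under `config$output_dir` with fixed precision, logs the gene counts
#' surviving each filter, and the run ends with a manifest (config hash,
#' per-file MD5 checksums, package version). Re-running with the same
#' config reproduces byte-identical tables and hence identical checksums.
#'
#' @param config a config list from [read_pipeline_config()] /
#'   [default_pipeline_config()], or a YAML path.
#' @param output_dir optional override of `config$output_dir`.
#' @return the run manifest (invisibly also written as `manifest.json`).
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         output_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- utils::modifyList(default_pipeline_config(), config)
  if (!is.null(output_dir)) config$output_dir <- output_dir
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  digits <- config$precision
  seed <- as.integer(config$seed)
  st <- config$stages
  state <- list()
  written <- character(0)
  emit <- function(tab, name) {
    path <- file.path(out, name)
    write_results_table(tab, path, digits = digits)
    written <<- c(written, path)
    path
  }

  ## ---- simulate or ingest -------------------------------------------------
  if (isTRUE(st$simulate)) {
    sc <- config$simulate$counts
    planted <- data.frame(gene = seq_len(sc$n_planted),
                          log2fc = rep(sc$planted_log2fc, sc$n_planted))
    sim_c <- simulate_counts(sc$n_genes, sc$samples_per_group,
                             baseline_mean = sc$baseline_mean,
                             dispersion = sc$dispersion,
                             planted_degs = planted,
                             seed = derive_seed(seed, "simulate_counts"))
    stc <- config$simulate$timecourse
    prof_universe <- enumerate_profiles(4L, config$profiles$c)
    n_prof <- nrow(prof_universe$changes)
    planted_tc <- data.frame(
      gene = seq_len(stc$n_planted),
      profile_id = rep_len(seq_len(n_prof), stc$n_planted))
    sim_t <- simulate_timecourse(stc$n_genes, prof_universe,
                                 planted_profiles = planted_tc,
                                 step_size = stc$step_size,
                                 noise_sd = stc$noise_sd,
                                 replicates = stc$replicates,
                                 seed = derive_seed(seed, "simulate_timecourse"))
    sx <- config$simulate$coexpression
    sim_x <- simulate_coexpression(sx$n_genes, sx$n_samples,
                                   module_members = seq_len(sx$module_size),
                                   loading_hub = sx$loading_hub,
                                   loading_member = sx$loading_member,
                                   seed = derive_seed(seed, "simulate_coexpr"))
    state$counts <- sim_c$matrix
    state$counts_ann <- sim_c$annotation
    state$series <- sim_t$matrix
    state$series_ann <- sim_t$annotation
    state$coexpr <- sim_x$matrix
    state$truth <- list(degs = sim_c$truth, profiles = sim_t$truth,
                        hub = sim_x$truth$hub, module = sim_x$truth$module)
    state$focus_set <- gene_set("FOCUS", sim_c$truth$gene_id,
                                "planted differential genes (synthetic focus set)")
    write_expression_matrix(sim_c$matrix, file.path(out, "counts.tsv"))
    write_expression_matrix(sim_t$matrix, file.path(out, "timecourse.tsv"))
    write_expression_matrix(sim_x$matrix, file.path(out, "coexpr.tsv"))
    written <- c(written, file.path(out, c("counts.tsv", "timecourse.tsv",
                                           "coexpr.tsv")))
    emit(sim_c$truth, "truth_degs.tsv")
    emit(sim_t$truth, "truth_profiles.tsv")
    message(sprintf("simulate: %d genes x %d samples (counts), %d planted DEGs",
                    nrow(sim_c$matrix$values), ncol(sim_c$matrix$values),
                    nrow(sim_c$truth)))
  } else {
    inp <- config$inputs
    read_meta <- function(path) {
      m <- read_results_table(path)
      sample_annotation(m$sample_id, m$group,
                        time_point = m[["time_point"]],
                        replicate = m[["replicate"]])
    }
    if (!is.null(inp$counts)) {
      state$counts <- read_expression_matrix(inp$counts, "counts")
      state$counts_ann <- read_meta(inp$meta)
    }
    if (!is.null(inp$series)) {
      state$series <- read_expression_matrix(inp$series, "log2")
      state$series_ann <- read_meta(inp$series_meta)
    }
    if (!is.null(inp$coexpr)) {
      state$coexpr <- read_expression_matrix(inp$coexpr, "log2")
    }
    if (!is.null(inp$focus_gmt)) {
      state$focus_set <- read_gene_sets_gmt(inp$focus_gmt)[[1L]]
    }
    if (!is.null(inp$deg)) state$deg <- read_results_table(inp$deg)
  }

  ## ---- differential expression -------------------------------------------
  if (isTRUE(st$diffexp)) {
    counts <- pipeline_need(state, "counts", "simulate")
    dx <- config$diffexp
    deg <- test_differential(counts, state$counts_ann)
    deg <- classify_deg(deg, deg_gates(dx$fc_up, dx$fc_down, dx$alpha,
                                       dx$alpha_kind))
    state$deg <- deg
    emit(deg, "deg.tsv")
    message(sprintf("diffexp: %d genes tested -> %d up, %d down",
                    nrow(deg), sum(deg$status == "up"),
                    sum(deg$status == "down")))
  }

  ## ---- overlap with the focus set ----------------------------------------
  if (isTRUE(st$overlap)) {
    deg <- pipeline_need(state, "deg", "diffexp")
    focus <- pipeline_need(state, "focus_set", "simulate")
    called <- deg$gene_id[deg$status != "ns"]
    ov <- if (length(called)) {
      intersect_sets(gene_set("DEG", called), focus)
    } else {
      structure(list(set_a_name = "DEG", set_b_name = focus$name,
                     only_a = character(0), both = character(0),
                     only_b = focus$members,
                     counts = c(only_a = 0L, both = 0L,
                                only_b = length(focus$members))),
                class = "overlap_result")
    }
    state$overlap <- ov
    emit(data.frame(part = rep(c("only_a", "both", "only_b"),
                               c(length(ov$only_a), length(ov$both),
                                 length(ov$only_b))),
                    gene_id = c(ov$only_a, ov$both, ov$only_b),
                    stringsAsFactors = FALSE),
         "overlap.tsv")
    message(sprintf("overlap: %d DEGs, %d in focus set",
                    length(called), ov$counts[["both"]]))
  }

  ## ---- z-score composite --------------------------------------------------
  if (isTRUE(st$zscore)) {
    counts <- pipeline_need(state, "counts", "simulate")
    focus <- pipeline_need(state, "focus_set", "simulate")
    nrm <- normalize_median_of_ratios(counts)
    logmat <- log2(nrm$normalized + 1)
    zc <- zscore_composite(logmat, focus, state$counts_ann)
    state$zscore <- zc
    emit(zc$scores, "zscore.tsv")
    message(sprintf("zscore: Mann-Whitney p = %.3g on the focus composite",
                    zc$p_value))
  }

  ## ---- time-course profiles ----------------------------------------------
  if (isTRUE(st$profiles)) {
    series <- pipeline_need(state, "series", "simulate")
    pc <- config$profiles
    universe <- enumerate_profiles(length(levels(state$series_ann$time_point)),
                                   pc$c)
    asg <- assign_profiles(series, universe, step_size = pc$step_size,
                           annotation = state$series_ann)
    sig <- profile_significance(asg, series, universe,
                                step_size = pc$step_size,
                                n_permutations = pc$n_permutations,
                                seed = derive_seed(seed, "profiles"),
                                annotation = state$series_ann)
    state$profile_assignments <- asg
    state$profile_significance <- sig
    emit(universe$table, "profile_universe.tsv")
    emit(asg, "profile_assignments.tsv")
    emit(sig, "profile_significance.tsv")
    message(sprintf("profiles: %d model profiles, %d significant (fdr < 0.05)",
                    nrow(universe$changes), sum(sig$fdr < 0.05)))
  }

  ## ---- term enrichment -----------------------------------------------------
  if (isTRUE(st$enrichment)) {
    deg <- pipeline_need(state, "deg", "diffexp")
    counts <- pipeline_need(state, "counts", "simulate")
    ec <- config$enrichment
    universe <- gene_set("UNIVERSE", rownames(counts$values))
    terms <- state$terms
    if (is.null(terms)) {
      focus <- pipeline_need(state, "focus_set", "simulate")
      terms <- synthesize_terms(universe$members, focus$members,
                                n_terms = ec$n_terms, term_size = ec$term_size,
                                seed = derive_seed(seed, "terms"))
      write_gene_sets_gmt(terms, file.path(out, "terms.gmt"))
      written <- c(written, file.path(out, "terms.gmt"))
    }
    up <- deg$gene_id[deg$status == "up"]
    if (!length(up)) up <- deg$gene_id[deg$status != "ns"]
    enr <- fisher_enrich(gene_set("DEG_UP", up), terms, universe)
    state$enrichment <- enr
    emit(enr, "enrichment.tsv")
    message(sprintf("enrichment: %d terms tested, %d with fdr < 0.05",
                    nrow(enr), sum(enr$fdr < 0.05)))
  }

  ## ---- GSEA ----------------------------------------------------------------
  if (isTRUE(st$gsea)) {
    counts <- pipeline_need(state, "counts", "simulate")
    gc <- config$gsea
    sets <- state$gsea_sets
    if (is.null(sets)) {
      focus <- pipeline_need(state, "focus_set", "simulate")
      sets <- synthesize_terms(rownames(counts$values), focus$members,
                               n_terms = gc$n_random_sets,
                               term_size = gc$set_size,
                               seed = derive_seed(seed, "gsea_sets"))
      write_gene_sets_gmt(sets, file.path(out, "gsea_sets.gmt"))
      written <- c(written, file.path(out, "gsea_sets.gmt"))
    }
    gs <- gsea_significance(counts, state$counts_ann, sets,
                            n_permutations = gc$n_permutations,
                            seed = derive_seed(seed, "gsea"),
                            metric = gc$metric, weight_p = gc$weight_p)
    state$gsea <- gs
    emit(gs, "gsea.tsv")
    message(sprintf("gsea: %d sets, %d with p < 0.05", nrow(gs),
                    sum(gs$p_value < 0.05)))
  }

  ## ---- co-expression network ----------------------------------------------
  if (isTRUE(st$network)) {
    coexpr <- pipeline_need(state, "coexpr", "simulate")
    nc <- config$network
    net <- build_network(coexpr, fdr_max = nc$fdr_max, r_min = nc$r_min)
    hubs <- rank_hubs(net)
    state$network <- net
    state$hubs <- hubs
    emit(net$edges, "network_edges.tsv")
    emit(hubs, "hubs.tsv")
    write_network_graphml(net, file.path(out, "network.graphml"))
    written <- c(written, file.path(out, "network.graphml"))
    message(sprintf("network: %d edges at fdr < %g; top hub %s (coreness %d)",
                    nrow(net$edges), nc$fdr_max,
                    if (nrow(hubs)) hubs$gene_id[1L] else "none",
                    if (nrow(hubs)) hubs$coreness[1L] else 0L))
  }

  ## ---- recovery report (synthetic runs only) -------------------------------
  if (!is.null(state$truth)) {
    emit(recovery_report(state), "recovery.tsv")
  }

  manifest <- write_manifest(config, written, out)
  invisible(manifest)
}

# random annotation terms, the first one enriched for the signal genes
synthesize_terms <- function(universe, signal, n_terms, term_size, seed) {
  with_rng_seed(seed, {
    sets <- vector("list", n_terms)
    take <- min(term_size, length(signal))
    sets[[1L]] <- gene_set("SIGNAL_TERM",
                           c(sample(signal, take),
                             sample(setdiff(universe, signal),
                                    max(term_size - take, 0L))),
                           "term planted to over-represent the signal genes")
    for (j in seq_len(n_terms - 1L)) {
      sets[[j + 1L]] <- gene_set(sprintf("RANDOM_TERM_%02d", j),
                                 sample(universe, term_size),
                                 "uniformly drawn background term")
    }
    stats::setNames(sets, vapply(sets, `[[`, character(1L), "name"))
  })
}

# score every stage against the generator truth tables
recovery_report <- function(state) {
  rows <- list()
  add <- function(metric, value) {
    rows[[length(rows) + 1L]] <<- data.frame(metric = metric, value = value,
                                             stringsAsFactors = FALSE)
  }
  tr <- state$truth
  if (!is.null(state$deg)) {
    called <- state$deg$gene_id[state$deg$status != "ns"]
    add("deg_sensitivity",
        length(intersect(called, tr$degs$gene_id)) / nrow(tr$degs))
    add("deg_false_calls", length(setdiff(called, tr$degs$gene_id)))
  }
  if (!is.null(state$profile_assignments) && nrow(tr$profiles)) {
    asg <- state$profile_assignments
    hit <- asg$profile_id[match(tr$profiles$gene_id, asg$gene_id)] ==
      tr$profiles$profile_id
    add("profile_recovery", mean(hit))
  }
  if (!is.null(state$hubs) && nrow(state$hubs)) {
    add("hub_rank_of_true_hub",
        state$hubs$rank[state$hubs$gene_id == tr$hub])
  }
  if (!is.null(state$zscore)) add("zscore_mw_p", state$zscore$p_value)
  if (!is.null(state$enrichment)) {
    sig_row <- state$enrichment[state$enrichment$term_name == "SIGNAL_TERM", ]
    if (nrow(sig_row)) add("signal_term_fdr", sig_row$fdr[1L])
  }
  if (!is.null(state$gsea)) {
    sig_row <- state$gsea[state$gsea$set_name == "SIGNAL_TERM", ]
    if (nrow(sig_row)) add("signal_set_gsea_p", sig_row$p_value[1L])
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

write_manifest <- function(config, files, out) {
  cfg_file <- tempfile(fileext = ".yaml")
  on.exit(unlink(cfg_file))
  config$output_dir <- NULL  # hash the analysis, not where it was written
  yaml::write_yaml(config, cfg_file)
  files <- sort(unique(files))
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_file)),
    version = as.character(utils::packageVersion("lysoflux")),
    files = lapply(stats::setNames(files, basename(files)),
                   function(f) unname(tools::md5sum(f)))
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest
}
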