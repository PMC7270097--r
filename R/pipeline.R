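## End-to-end orchestration: stats -> tree -> selection scans -> consensus ->
## regional frequencies -> control region -> environment GLM, from a single
## validated config, with stage-named errors and a deterministic run manifest.

#' Build and validate a pipeline configuration
#'
#' @param x named list (or YAML file path) overriding the defaults. Main
#'   fields: `seed`; `simulate` (list: `enabled`, `n_taxa`, `n_codons`,
#'   `n_control`, `effect_size`, `n_per_region`); `inputs` (list of paths:
#'   `coding_fasta`, `tree`, `control_fasta`, `climatology`) used when
#'   simulation is disabled; `thresholds` (`posterior`, `episodic_p`,
#'   `physchem_category`, `physchem_p`, `min_methods`); `policy`; `out_dir`.
#' @return validated config list of class `pipeline_config`
#' @export
pipeline_config <- function(x = list()) {
  if (is.character(x)) x <- yaml::read_yaml(x)
  defaults <- list(
    seed = 1,
    simulate = list(enabled = TRUE, n_taxa = 12, n_codons = 60,
                    n_control = 24, effect_size = 2, n_per_region = 40),
    inputs = list(coding_fasta = NULL, tree = NULL, control_fasta = NULL,
                  climatology = NULL),
    thresholds = list(posterior = 0.9, episodic_p = 0.05,
                      physchem_category = 6, physchem_p = 0.001,
                      min_methods = 2),
    policy = "complete",
    out_dir = file.path(tempdir(), "mitoscan_out")
  )
  cfg <- utils::modifyList(defaults, x)
  th <- cfg$thresholds
  if (!is.numeric(th$posterior) || th$posterior <= 0 || th$posterior > 1) {
    stop("invalid threshold: posterior must be in (0, 1]", call. = FALSE)
  }
  if (th$episodic_p <= 0 || th$episodic_p >= 1) {
    stop("invalid threshold: episodic_p must be in (0, 1)", call. = FALSE)
  }
  if (!th$physchem_category %in% 1:8) {
    stop("invalid threshold: physchem_category must be in 1..8", call. = FALSE)
  }
  if (th$physchem_p <= 0 || th$physchem_p >= 1) {
    stop("invalid threshold: physchem_p must be in (0, 1)", call. = FALSE)
  }
  if (!th$min_methods %in% 1:3) {
    stop("invalid threshold: min_methods must be 1, 2 or 3", call. = FALSE)
  }
  if (!cfg$policy %in% c("complete", "pairwise")) {
    stop("invalid policy", call. = FALSE)
  }
  # normalize: unset input paths are simply absent (so a config serialized to
  # YAML/JSON and read back compares equal)
  cfg$inputs <- cfg$inputs[!vapply(cfg$inputs, is.null, logical(1))]
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Produces a per-partition diversity/neutrality report, a consensus
#' selected-site report with per-region carrier frequencies, a control-region
#' annotation report, an environment-GLM report, and a run manifest (seeds,
#' thresholds, stage counts, config hash). Any stage failure aborts with a
#' stage-named error; reports already written are retained and the manifest
#' flags the run as partial.
#'
#' @param config a [pipeline_config()] (or list/path coerced through it)
#' @return list of class `pipeline_result` with report paths and in-memory
#'   results, invisibly
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, thresholds = config$thresholds,
                   policy = config$policy, stages = list(), partial = FALSE)
  res <- list()

  finish_manifest <- function() {
    cfg_json <- file.path(config$out_dir, "config.json")
    jsonlite::write_json(unclass(config), cfg_json, auto_unbox = TRUE,
                         pretty = TRUE, null = "null")
    manifest$config_hash <<- unname(tools::md5sum(cfg_json))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  run_stage <- function(name, expr) {
    out <- tryCatch(expr, error = function(e) {
      manifest$partial <<- TRUE
      manifest$failed_stage <<- name
      finish_manifest()
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    out
  }

  ## inputs
  inp <- run_stage("inputs", {
    if (isTRUE(config$simulate$enabled)) {
      s <- config$seed
      tree <- simulate_tree(config$simulate$n_taxa, "coalescent", seed = s,
                            target_height = 1)
      sim <- simulate_codon_alignment(tree, config$simulate$n_codons,
                                      seed = s + 1)
      cr <- simulate_control_regions(config$simulate$n_control, seed = s + 2)
      env <- simulate_env_glm_dataset(config$simulate$effect_size,
                                      config$simulate$n_per_region,
                                      seed = s + 3)
      regions <- setNames(rep(c("NAS", "SEAS", "BoB"),
                              length.out = length(sim$caln$ids)),
                          sim$caln$ids)
      list(caln = sim$caln, tree = tree, control = cr$seqs, env = env,
           regions = regions, clim = read_climatology())
    } else {
      aln <- read_fasta(config$inputs$coding_fasta)
      caln <- to_codon_alignment(aln)
      tree <- if (!is.null(config$inputs$tree)) read_newick(config$inputs$tree)
      else NULL
      control <- if (!is.null(config$inputs$control_fasta)) {
        read_fasta(config$inputs$control_fasta)$seqs
      } else NULL
      clim <- if (!is.null(config$inputs$climatology)) {
        read_climatology(config$inputs$climatology)
      } else read_climatology()
      regions <- aln$metadata$region
      if (is.null(regions)) {
        regions <- setNames(rep(c("NAS", "SEAS", "BoB"),
                                length.out = length(aln$ids)), aln$ids)
      }
      list(caln = caln, tree = tree, control = control, env = NULL,
           regions = regions, clim = clim)
    }
  })

  ## diversity / neutrality stats
  res$stats <- run_stage("stats", {
    aln <- codon_to_nucleotide(inp$caln)
    nt <- neutrality_tests(aln, config$policy)
    ds <- nt$stats
    kk <- nei_gojobori(inp$caln)
    df <- data.frame(
      partition = "coding", n = ds$n, L = ds$L, S = ds$S, pi = ds$pi,
      n_hap = ds$n_hap, Hd = ds$Hd, K = ds$K, theta = ds$theta_w,
      Ka = kk$Ka, Ks = kk$Ks, KaKs = kk$ratio,
      tajima_d = nt$tajima_d, tajima_label = nt$tajima_label,
      fu_li_d_star = nt$fu_li_d_star, fu_li_f_star = nt$fu_li_f_star,
      fu_fs = nt$fu_fs)
    .write_tsv(df, file.path(config$out_dir, "diversity_stats.tsv"))
    manifest$stages$stats <- list(partitions = 1L, S = ds$S)
    df
  })

  ## tree
  tree <- run_stage("tree", {
    if (is.null(inp$tree)) nj_fallback_tree(codon_to_nucleotide(inp$caln))
    else inp$tree
  })

  ## selection scans + consensus
  res$selection <- run_stage("selection", {
    th <- config$thresholds
    gs <- grid_bayes_scan(inp$caln, tree, pos_threshold = th$posterior)
    es <- episodic_scan(inp$caln, tree, p_threshold = th$episodic_p)
    ps <- physchem_scan(inp$caln, tree, min_category = th$physchem_category,
                        p_threshold = th$physchem_p)
    cons <- consensus_positive_sites(gs, es, ps$sites,
                                     n_sites = inp$caln$n_codons,
                                     min_methods = th$min_methods)
    .write_tsv(cons, file.path(config$out_dir, "selected_sites.tsv"))
    manifest$stages$selection <- list(
      sites_scanned = inp$caln$n_codons,
      grid_flagged = sum(gs$sites$flagged_positive),
      episodic_flagged = sum(es$flagged),
      physchem_flagged = length(ps$sites),
      consensus = sum(cons$consensus_positive),
      excluded = length(gs$excluded))
    list(grid = gs, episodic = es, physchem = ps, consensus = cons)
  })

  ## regional carrier frequencies of consensus sites
  res$frequencies <- run_stage("frequencies", {
    sites <- res$selection$consensus$site[res$selection$consensus$consensus_positive]
    aa_mat <- inp$caln$aa
    rownames(aa_mat) <- inp$caln$ids
    fr <- selected_site_frequencies(sites, aa_mat, inp$regions)
    .write_tsv(fr$per_site, file.path(config$out_dir, "site_frequencies.tsv"))
    manifest$stages$frequencies <- list(sites = length(sites))
    fr
  })

  ## control region
  res$control_region <- run_stage("control_region", {
    if (is.null(inp$control)) return(NULL)
    catalog <- read_unit_catalog()
    rows <- list()
    for (id in names(inp$control)) {
      ann <- detect_tandem_repeats(inp$control[[id]], catalog = catalog)
      if (nrow(ann) == 0) {
        rows[[id]] <- data.frame(id = id, type = "none", subtype = NA,
                                 copies = 0, period = NA, dG = NA,
                                 dG_per_length = NA, stringsAsFactors = FALSE)
        next
      }
      a <- ann[1, ]
      cl <- classify_repeat_type(a, catalog)
      fold <- fold_min_energy(a$unit, "rna")
      rows[[id]] <- data.frame(id = id, type = cl$type, subtype = cl$subtype,
                               copies = a$copies, period = a$period,
                               dG = fold$energy,
                               dG_per_length = fold$dG_per_length,
                               stringsAsFactors = FALSE)
    }
    rep_tab <- do.call(rbind, rows)
    .write_tsv(rep_tab, file.path(config$out_dir, "control_region.tsv"))
    motif_tab <- annotate_motifs(inp$control[[1]])
    .write_tsv(motif_tab, file.path(config$out_dir, "control_region_motifs.tsv"))
    manifest$stages$control_region <- list(
      n = length(inp$control),
      typed = sum(rep_tab$type != "none"))
    list(repeats = rep_tab, motifs = motif_tab)
  })

  ## environment GLM
  res$env <- run_stage("env_glm", {
    cs <- seasonal_summaries(inp$clim)
    per_region <- if (!is.null(inp$env)) {
      ag <- stats::aggregate(carrier ~ region, inp$env$individuals, sum)
      tot <- table(inp$env$individuals$region)
      data.frame(region = ag$region, carriers = ag$carrier,
                 total = as.integer(tot[ag$region]))
    } else {
      res$frequencies$per_region[, c("region", "carriers", "total")]
    }
    assoc <- env_association(per_region, cs)
    .write_tsv(assoc, file.path(config$out_dir, "env_glm.tsv"))
    manifest$stages$env_glm <- list(models = nrow(assoc))
    list(summaries = cs, per_region = per_region, association = assoc)
  })

  finish_manifest()
  res$manifest <- manifest
  res$out_dir <- config$out_dir
  class(res) <- "pipeline_result"
  invisible(res)
}
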