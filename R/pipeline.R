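# Stage orchestration: each subcommand reads its inputs, runs the
# corresponding analysis, and writes machine-readable TSV/JSON artifacts
# plus a run manifest (hashed inputs, seed, parameters, package version)
# sufficient to re-execute the run.

pipeline_defaults <- function() {
  list(fasta = NULL, evidence = NULL, sites = NULL, annotations = NULL,
       replicate_col = "replicate", collapse_families = TRUE,
       term = "structural constituent of cytoskeleton",
       motifs = NULL, n_sims = 1e5, seed = 1L, fdr = 0.05, fwer = 0.05,
       sided = "two", out = ".", verbose = FALSE)
}

merge_config <- function(defaults, ...) {
  for (cfg in list(...)) {
    if (is.null(cfg)) next
    for (nm in names(cfg)) defaults[[nm]] <- cfg[[nm]]
  }
  defaults
}

pipeline_log <- function(cfg, ...) {
  message("[degradomics] ", ...)
}

write_manifest <- function(cfg, subcommand, inputs, outputs) {
  inputs <- inputs[!vapply(inputs, is.null, TRUE)]
  hashes <- lapply(inputs, function(p)
    unname(tools::md5sum(p)))
  man <- list(subcommand = subcommand,
              package = "degradomics",
              version = as.character(utils::packageVersion("degradomics")),
              parameters = cfg[setdiff(names(cfg), "verbose")],
              input_md5 = hashes,
              outputs = outputs)
  path <- file.path(cfg$out, paste0("manifest-", subcommand, ".json"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

load_events <- function(cfg) {
  if (!is.null(cfg$sites)) {
    ev <- read_site_table(cfg$sites)
  } else if (!is.null(cfg$evidence)) {
    if (is.null(cfg$fasta)) stop("evidence input requires --fasta")
    prot <- read_proteome(cfg$fasta)
    ev <- extract_cleavage_sites(
      read_evidence(cfg$evidence, replicate_col = cfg$replicate_col), prot)
  } else stop("need --sites or --evidence")
  collapse_family_duplicates(ev, collapse = isTRUE(cfg$collapse_families))
}

#' Run a pipeline stage
#'
#' Subcommands: `simulate` (write a synthetic degradome), `extract`
#' (peptide evidence -> site table), `consensus` (60-motif enrichment
#' table), `annotate` (term enrichment of motif-bearing substrates),
#' `scoc-mc` (Monte Carlo single-motif screen), `pairs` (Monte Carlo pair
#' screen + pair points), `select` (stepwise candidate selection from a
#' pair screen), `meta-test` (analytic consensus-overlap test). Every
#' stage writes its TSV/JSON artifacts and a run manifest into
#' `config$out`.
#'
#' @param subcommand One of the stage names above.
#' @param config Named list of options overriding the defaults (input
#'   paths `fasta`, `evidence`, `sites`, `annotations`; `replicate_col`;
#'   `collapse_families`; `term`; `motifs`; `n_sims`; `seed`; `fdr`;
#'   `fwer`; `sided`; output directory `out`).
#' @return Invisibly a named list of written artifact paths (for
#'   `meta-test`, the p-value).
#' @export
run_pipeline <- function(subcommand, config = list()) {
  cfg <- merge_config(pipeline_defaults(), config)
  if (cfg$fdr <= 0 || cfg$fdr >= 1 || cfg$fwer <= 0 || cfg$fwer >= 1)
    stop("fdr and fwer must lie in (0, 1)")
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  switch(subcommand,
    "simulate" = {
      gen_args <- config[intersect(names(config),
                                   names(formals(synthetic_config)))]
      gen_args$seed <- cfg$seed
      x <- generate_degradome(do.call(synthetic_config, gen_args))
      paths <- write_degradome(x, cfg$out)
      write_manifest(cfg, subcommand, list(), as.list(paths))
      pipeline_log(cfg, "simulated ", nrow(x$events), " events")
      invisible(as.list(paths))
    },
    "extract" = {
      ev <- load_events(cfg)
      out <- file.path(cfg$out, "sites.tsv")
      write_site_table(ev, out)
      log <- attr(ev, "merge_log")
      log_path <- file.path(cfg$out, "family-merge-log.tsv")
      utils::write.table(log, log_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      write_manifest(cfg, subcommand,
                     list(fasta = cfg$fasta, evidence = cfg$evidence,
                          sites = cfg$sites),
                     list(sites = out, merge_log = log_path))
      pipeline_log(cfg, nrow(ev), " cleavage events (",
                   nrow(log), " family duplicates merged)")
      invisible(list(sites = out, merge_log = log_path))
    },
    "consensus" = {
      ev <- load_events(cfg)
      prot <- read_proteome(cfg$fasta)
      ct <- consensus_table(ev, prot, alpha = cfg$fdr)
      out <- file.path(cfg$out, "consensus.tsv")
      write_consensus_table(ct, out)
      write_manifest(cfg, subcommand,
                     list(fasta = cfg$fasta, evidence = cfg$evidence,
                          sites = cfg$sites), list(consensus = out))
      pipeline_log(cfg, "consensus: ",
                   summary(ct)$consensus)
      invisible(list(consensus = out))
    },
    "annotate" = {
      ev <- load_events(cfg)
      ann <- read_annotations(cfg$annotations)
      if (is.null(cfg$motifs)) stop("annotate requires --motifs (comma-separated)")
      fg <- motif_foreground(ev, cfg$motifs)
      bg <- unique(ev$accession)
      te <- term_enrichment(fg, bg, ann, alpha = cfg$fdr)
      out <- file.path(cfg$out, "term-enrichment.tsv")
      utils::write.table(te, out, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      write_manifest(cfg, subcommand,
                     list(sites = cfg$sites, evidence = cfg$evidence,
                          annotations = cfg$annotations),
                     list(term_enrichment = out))
      invisible(list(term_enrichment = out))
    },
    "scoc-mc" = ,
    "pairs" = {
      ev <- load_events(cfg)
      ann <- read_annotations(cfg$annotations)
      flagged <- annotation_flags(ann, cfg$term)
      targets <- if (!is.null(cfg$motifs)) cfg$motifs
                 else if (subcommand == "pairs") motif_pairs() else motifs()
      sc <- mc_screen(ev, flagged, targets, n_sims = cfg$n_sims,
                      seed = cfg$seed, sided = cfg$sided, alpha = cfg$fdr)
      out <- file.path(cfg$out, paste0(subcommand, "-screen.tsv"))
      write_mc_screen(sc, out)
      outputs <- list(screen = out)
      if (subcommand == "pairs") {
        total <- observed_protein_cleavages(ev, flagged)
        singles <- vapply(motifs(), function(m)
          observed_protein_cleavages(ev, flagged, m), 0L)
        pts <- pair_points(sc, total)
        pts <- eligibility_filter(pts, singles)
        pts_path <- file.path(cfg$out, "pair-points.tsv")
        utils::write.table(pts, pts_path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        outputs$pair_points <- pts_path
      }
      write_manifest(cfg, subcommand,
                     list(sites = cfg$sites, evidence = cfg$evidence,
                          annotations = cfg$annotations), outputs)
      pipeline_log(cfg, sum(sc$q_fdr < cfg$fdr), " target(s) at q < ",
                   cfg$fdr)
      invisible(outputs)
    },
    "select" = {
      if (is.null(cfg$pair_points)) stop("select requires pair_points path")
      pts <- read_delim_sniff(cfg$pair_points)
      pts$eligible <- as.logical(pts$eligible)
      cand <- select_candidates(pts,
                                bonferroni_cutoff(nrow(pts), cfg$fwer))
      out <- file.path(cfg$out, "candidates.tsv")
      utils::write.table(as.data.frame(cand), out, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      write_manifest(cfg, subcommand, list(pair_points = cfg$pair_points),
                     list(candidates = out))
      pipeline_log(cfg, nrow(cand), " candidate pair(s)")
      invisible(list(candidates = out))
    },
    "meta-test" = {
      mt <- cfg$meta
      if (is.null(mt) || length(mt) != 4)
        stop("meta-test requires meta = c(population, consensus, drawn, overlap)")
      p <- consensus_overlap_test(mt[1], mt[2], mt[3], mt[4])
      cat(format(p, digits = 6), "\n")
      invisible(list(p = p))
    },
    stop("unknown subcommand: ", subcommand)
  )
}
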