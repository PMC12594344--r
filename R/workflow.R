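.dist_to_spec <- function(d) c(list(family = d$family), d$params)

.spec_to_dist <- function(x) {
  if (inherits(x, "fragment_dist")) return(x)
  do.call(fragment_dist, x)
}

#' Pipeline configuration
#'
#' Collects every tunable parameter of the simulate-classify-segment-map
#' pipeline with validated defaults. Unknown keys are rejected. The
#' resolved configuration is written next to the outputs of every run, so
#' results are a pure function of (configuration, seed).
#'
#' @param ... Key-value overrides of the defaults (see
#'   `names(pipeline_config())` and the methods vignette for meanings and
#'   units).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    out_dir = NULL,
    seed = 1L,
    genome_length = 1e6,
    divergence = 0.01,
    accessory = NULL,
    marker_position = 5e5,
    marker_dist = list(family = "log_uniform", low = 1e4, high = 5e5),
    extra_count = list(family = "poisson", lambda = 1.2),
    extra_dist = list(family = "log_uniform", low = 5e3, high = 5e4),
    placement_window = 5e5,
    genome_wide = FALSE,
    forbidden = NULL,
    n_clones = 10L,
    depth = 10,
    total_depth = 100,
    read_length = 150L,
    error_rate = 1e-3,
    hmm_e_d = 0.95, hmm_e_r = 0.05, hmm_t = 1e-3, hmm_pi_d = 0.5,
    hmm_em = FALSE,
    cp_penalty = 3, cp_min_segment_sites = 2L,
    bin_size = 1000L,
    pseudocount = 1,
    peak_delta = log10(2),
    log_level = "info")
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0L)
    stopf("unknown configuration key(s): %s",
          paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, over, keep.null = TRUE)
  structure(cfg, class = "pipeline_config")
}

.write_resolved_config <- function(cfg, dir) {
  x <- unclass(cfg)
  x$package_version <- as.character(utils::packageVersion("hfrmap"))
  jsonlite::write_json(x, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

.log_msg <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(sprintf(...))
}

.simulate_cross <- function(cfg) {
  pair <- generate_genome_pair(genome_pair_config(
    genome_length = cfg$genome_length, divergence = cfg$divergence,
    accessory_segments = cfg$accessory, seed = cfg$seed))
  clone_seeds <- with_seed(cfg$seed + 1L,
                           sample.int(.Machine$integer.max, cfg$n_clones))
  clones <- lapply(seq_len(cfg$n_clones), function(i) {
    simulate_recombinant(
      pair, cfg$marker_position,
      marker_dist = .spec_to_dist(cfg$marker_dist),
      extra_count = cfg$extra_count,
      extra_dist = .spec_to_dist(cfg$extra_dist),
      placement_window = cfg$placement_window,
      genome_wide = cfg$genome_wide,
      forbidden = cfg$forbidden,
      clone_id = sprintf("clone_%02d", i),
      seed = clone_seeds[i])
  })
  list(pair = pair, clones = clones)
}

#' End-to-end per-clone recombination-tract analysis
#'
#' Simulates (or accepts) a cross, sequences each recombinant clone,
#' classifies the reads competitively, delineates donor tracts with both
#' the HMM and the changepoint method, compares the two, and summarizes
#' fragment statistics. When `out_dir` is set in the configuration, per
#' clone BED files (both methods and the truth), a concordance table, the
#' fragment summary and the resolved configuration are written there.
#'
#' @param config A [pipeline_config()].
#' @param pair Optional pre-built `genome_pair` (skips simulation of the
#'   genomes; clones are still simulated unless `clones`/`reads` given).
#' @param clones Optional list of `recombinant` objects.
#' @param reads Optional list of read `data.frame`s, one per clone.
#' @return A list of class `clone_analysis`: `pair`, `clones`,
#'   `fragments_hmm`, `fragments_cp` (per-clone lists), `concordance`
#'   (per-clone `data.frame`), `stats_hmm`, `stats_cp`
#'   ([fragment_stats()] on each method's calls).
#' @export
run_clone_analysis <- function(config = pipeline_config(), pair = NULL,
                               clones = NULL, reads = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(pair) || is.null(clones)) {
    sim <- .simulate_cross(config)
    if (is.null(pair)) pair <- sim$pair
    if (is.null(clones)) clones <- sim$clones
  }
  if (is.null(reads)) {
    read_seeds <- with_seed(config$seed + 2L,
                            sample.int(.Machine$integer.max,
                                       length(clones)))
    reads <- lapply(seq_along(clones), function(i) {
      simulate_reads(clones[[i]]$sequence, depth = config$depth,
                     read_length = config$read_length,
                     error_rate = config$error_rate,
                     seed = read_seeds[i],
                     id_prefix = clones[[i]]$clone_id)
    })
  }
  idx <- build_classifier_index(pair)
  sites <- pair$truth_sites
  hp <- hmm_params(config$hmm_e_d, config$hmm_e_r, config$hmm_t,
                   config$hmm_pi_d)
  cpp <- changepoint_params(config$cp_penalty, config$cp_min_segment_sites)
  marker <- config$marker_position

  frags_hmm <- list(); frags_cp <- list(); conc <- list()
  for (i in seq_along(clones)) {
    id <- clones[[i]]$clone_id
    cls <- classify_builtin(reads[[i]], pair, sites, index = idx)
    fh <- hmm_segment(binary_series(cls), hp, marker = marker,
                      em = config$hmm_em)
    fc <- changepoint_segment(site_frequencies(cls, sites), cpp,
                              marker = marker)
    cmp <- compare_methods(fh, fc)
    frags_hmm[[id]] <- fh
    frags_cp[[id]] <- fc
    conc[[id]] <- data.frame(
      clone_id = id, jaccard = cmp$jaccard,
      n_hmm = sum(fh$origin == "donor"),
      n_cp = sum(fc$origin == "donor"),
      n_matched = nrow(cmp$matched),
      unresolved = isTRUE(attr(fh, "unresolved")),
      stringsAsFactors = FALSE)
    .log_msg(config, "clone %s: %d HMM / %d changepoint fragments, J=%.3f",
             id, sum(fh$origin == "donor"), sum(fc$origin == "donor"),
             cmp$jaccard)
  }
  concordance <- do.call(rbind, conc)
  rownames(concordance) <- NULL
  res <- structure(list(
    pair = pair, clones = clones,
    fragments_hmm = frags_hmm, fragments_cp = frags_cp,
    concordance = concordance,
    stats_hmm = fragment_stats(frags_hmm, marker),
    stats_cp = fragment_stats(frags_cp, marker)),
    class = "clone_analysis")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (id in names(frags_hmm)) {
      write_fragments_bed(
        frags_hmm[[id]][frags_hmm[[id]]$origin == "donor", ],
        file.path(config$out_dir, paste0(id, "_hmm.bed")))
      write_fragments_bed(
        frags_cp[[id]][frags_cp[[id]]$origin == "donor", ],
        file.path(config$out_dir, paste0(id, "_changepoint.bed")))
      tr <- clones[[match(id, vapply(clones, `[[`, "", "clone_id"))]]
      bed <- tr$fragments
      bed$origin <- "truth"
      write_fragments_bed(bed, file.path(config$out_dir,
                                         paste0(id, "_truth.bed")))
    }
    write_tsv(concordance, file.path(config$out_dir, "concordance.tsv"))
    write_tsv(res$stats_cp$summary,
              file.path(config$out_dir, "fragment_summary.tsv"))
    write_tsv(res$stats_cp$fragments,
              file.path(config$out_dir, "fragments.tsv"))
    .write_resolved_config(config, config$out_dir)
  }
  res
}

#' End-to-end pooled-sequencing locus mapping
#'
#' Simulates (or accepts) a pool of selected recombinants, classifies the
#' pooled reads, bins them into a donor/recipient profile, localizes the
#' selected locus at the profile peak, and computes the decay profile
#' around it. When `out_dir` is set, the profile (TSV and BEDGRAPH), the
#' peak call (BED + JSON report) and the resolved configuration are
#' written.
#'
#' @param config A [pipeline_config()]; `total_depth` is the aggregate
#'   pool coverage.
#' @param pair,clones Optional pre-built inputs as in
#'   [run_clone_analysis()].
#' @param pool Optional pre-built `read_pool`.
#' @return A list of class `pool_analysis`: `pair`, `clones`, `pool`
#'   (manifest only unless simulated here), `profile`, `call`
#'   ([locate_selected_locus()]), `decay` ([decay_profile()]).
#' @export
run_pool_analysis <- function(config = pipeline_config(), pair = NULL,
                              clones = NULL, pool = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(pair) || is.null(clones)) {
    sim <- .simulate_cross(config)
    if (is.null(pair)) pair <- sim$pair
    if (is.null(clones)) clones <- sim$clones
  }
  if (is.null(pool)) {
    pool <- build_pool(clones, total_depth = config$total_depth,
                       read_length = config$read_length,
                       error_rate = config$error_rate,
                       seed = config$seed + 3L)
  }
  cls <- classify_builtin(pool$reads, pair, pair$truth_sites)
  profile <- bin_pool(cls$labels, nchar(pair$recipient_seq),
                      bin_size = config$bin_size,
                      pseudocount = config$pseudocount)
  call <- locate_selected_locus(profile, delta = config$peak_delta)
  decay <- decay_profile(profile, config$marker_position)
  .log_msg(config, "pool peak at %.0f (marker %.0f): offset %.0f bases",
           call$peak_position, config$marker_position,
           call$peak_position - config$marker_position)
  res <- structure(list(pair = pair, clones = clones, pool = pool,
                        classification = cls, profile = profile,
                        call = call, decay = decay),
                   class = "pool_analysis")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(as.data.frame(profile),
              file.path(config$out_dir, "pool_profile.tsv"))
    bg <- data.frame(chrom = "recipient",
                     start = profile$bin_start - 1L,
                     end = pmin(profile$bin_start - 1L +
                                  attr(profile, "bin_size"),
                                attr(profile, "genome_length")),
                     value = profile$log_ratio)
    utils::write.table(bg, file.path(config$out_dir,
                                     "pool_log_ratio.bedgraph"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    write_fragments_bed(
      data.frame(start = call$interval[1], end = call$interval[2],
                 origin = "peak_interval"),
      file.path(config$out_dir, "peak.bed"))
    jsonlite::write_json(
      list(peak_position = call$peak_position,
           peak_value = call$peak_value,
           interval = call$interval, tie = call$tie,
           half_decay_left = decay$half_decay_left,
           half_decay_right = decay$half_decay_right),
      file.path(config$out_dir, "peak_report.json"),
      auto_unbox = TRUE, digits = NA, null = "null")
    .write_resolved_config(config, config$out_dir)
  }
  res
}
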