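#' Simulation configuration
#'
#' Default scale — a 2 Mb genome, 200 true sites, 5 replicates, 200,000
#' reads per replicate — runs in seconds while leaving room for hundreds of
#' non-overlapping sites. Detection dropout (`p_detect`), boundary jitter
#' and replicate-private noise peaks emulate the failure modes seen in real
#' multi-replicate experiments: a caller missing a genuine site in some
#' replicates, imprecise boundaries, and spurious calls.
#'
#' @param genome named vector of chromosome lengths (default one 2 Mb
#'   chromosome "chrS").
#' @param n_sites number of true binding sites.
#' @param site_width_mean,site_width_sd site width distribution in bp.
#' @param n_replicates number of biological replicates.
#' @param p_detect per-replicate per-site probability a site is called.
#' @param jitter_sd sd in bp of called-peak boundary/summit noise.
#' @param reads_per_replicate reads per replicate (2 per pseudo-fragment).
#' @param enrichment_fraction fraction of fragments drawn from true sites
#'   (detected or not); the remainder is uniform background.
#' @param fragment_length,read_length bp. Pseudo-fragments emit a plus read
#'   at the fragment start and a minus read at its end, so the strand
#'   cross-correlation peaks near `fragment_length` by construction.
#' @param noise_sites_per_replicate spurious replicate-private peaks.
#' @param seed integer RNG seed; identical seeds give identical experiments.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(genome = c(chrS = 2e6),
                       n_sites = 200,
                       site_width_mean = 200, site_width_sd = 40,
                       n_replicates = 5,
                       p_detect = 0.8,
                       jitter_sd = 20,
                       reads_per_replicate = 200000,
                       enrichment_fraction = 0.3,
                       fragment_length = 150, read_length = 36,
                       noise_sites_per_replicate = 55,
                       seed = 1L) {
  stopifnot(p_detect >= 0, p_detect <= 1,
            enrichment_fraction >= 0, enrichment_fraction <= 1,
            n_replicates >= 1, fragment_length > read_length)
  structure(as.list(environment()), class = "sim_config")
}

# place n non-overlapping intervals of the given widths uniformly on [0, L)
place_sites <- function(n, widths, L, max_tries = 200) {
  for (t in seq_len(max_tries)) {
    start <- sort(sample.int(L - max(widths), n))
    end <- start + widths[order(order(start))]
    if (all(utils::head(end, -1) < utils::tail(start, -1)))
      return(data.frame(start = start, end = end))
  }
  stop("could not place ", n, " non-overlapping sites after ",
       max_tries, " tries")
}

#' Simulate a multi-replicate ChIP-seq experiment with known truth
#'
#' True sites are placed uniformly without overlap. Per replicate, each site
#' is independently detected with probability `p_detect`; detected sites
#' emit a called peak with boundaries jittered by centred Gaussian noise and
#' a summit at the (jittered) site centre, clamped so the peak always
#' overlaps its site. Noise peaks are placed uniformly away from true sites.
#' Reads come from pseudo-fragments: a fraction `enrichment_fraction` of
#' fragments centre near a true site (detected or not — dropout is a
#' property of the caller, not the chromatin), the rest are uniform
#' background; each fragment yields one plus read at its start and one
#' minus read at its end.
#'
#' @param config a [sim_config()].
#' @return object of class `sim_truth`: list with `config`, `sites`
#'   (chrom/start/end/center), `detected` (sites x replicates logical
#'   matrix), `peak_sets` (named list of `chip_peaks`, true + noise calls),
#'   `read_sets` (named list of `chip_reads`).
#' @export
simulate_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  gen <- chrom_sizes(config$genome)
  # sites per chromosome, proportional to length
  alloc <- round(config$n_sites * gen / sum(gen))
  alloc[1] <- config$n_sites - sum(alloc[-1])
  sites <- do.call(rbind, lapply(names(gen), function(ch) {
    n <- alloc[[ch]]
    if (n == 0) return(NULL)
    w <- pmax(50, round(stats::rnorm(n, config$site_width_mean,
                                     config$site_width_sd)))
    s <- place_sites(n, w, gen[[ch]])
    data.frame(chrom = ch, s)
  }))
  sites$center <- floor((sites$start + sites$end) / 2)
  sites$site_id <- sprintf("site_%04d", seq_len(nrow(sites)))
  ns <- nrow(sites)
  labels <- sprintf("rep%d", seq_len(config$n_replicates))
  detected <- matrix(stats::runif(ns * config$n_replicates) < config$p_detect,
                     nrow = ns, dimnames = list(sites$site_id, labels))
  jit <- function(n) round(stats::rnorm(n, 0, config$jitter_sd))

  peak_sets <- stats::setNames(lapply(labels, function(l) {
    i <- which(detected[, l])
    pk_true <- NULL
    if (length(i)) {
      s <- sites$start[i] + jit(length(i))
      e <- sites$end[i] + jit(length(i))
      # clamp: keep the call overlapping its site and nondegenerate
      s <- pmin(pmax(s, 0), sites$end[i] - 1)
      e <- pmax(pmin(e, gen[sites$chrom[i]]), sites$start[i] + 1)
      e <- pmax(e, s + 10)
      smt <- pmin(pmax(sites$center[i] + jit(length(i)), s), e - 1)
      pk_true <- data.frame(chrom = sites$chrom[i], start = s, end = e,
                            summit = smt, score = 0, replicate_id = l,
                            stringsAsFactors = FALSE)
    }
    pk_noise <- NULL
    nn <- config$noise_sites_per_replicate
    if (nn > 0) {
      w <- pmax(50, round(stats::rnorm(nn, config$site_width_mean,
                                       config$site_width_sd)))
      ch <- sample(names(gen), nn, replace = TRUE, prob = gen / sum(gen))
      st <- en <- numeric(nn)
      for (k in seq_len(nn)) {
        for (try in 1:100) {
          s0 <- sample.int(gen[[ch[k]]] - w[k], 1)
          on_site <- any(sites$chrom == ch[k] &
                           sites$start < s0 + w[k] & sites$end > s0)
          if (!on_site) break
        }
        st[k] <- s0; en[k] <- s0 + w[k]
      }
      pk_noise <- data.frame(chrom = ch, start = st, end = en,
                             summit = floor((st + en) / 2), score = 0,
                             replicate_id = l, stringsAsFactors = FALSE)
    }
    validate_peaks(sort_coords(rbind(pk_true, pk_noise)))
  }), labels)

  read_sets <- stats::setNames(lapply(labels, function(l) {
    n_frag <- round(config$reads_per_replicate / 2)
    n_enr <- round(config$enrichment_fraction * n_frag)
    fl <- config$fragment_length
    centers <- chroms <- NULL
    if (n_enr > 0) {
      i <- sample.int(ns, n_enr, replace = TRUE)
      spread <- pmax(10, (sites$end[i] - sites$start[i]) / 4)
      centers <- sites$center[i] + round(stats::rnorm(n_enr, 0, spread))
      chroms <- sites$chrom[i]
    }
    n_bg <- n_frag - n_enr
    if (n_bg > 0) {
      ch <- sample(names(gen), n_bg, replace = TRUE, prob = gen / sum(gen))
      centers <- c(centers,
                   floor(stats::runif(n_bg, 0, gen[ch] - fl)) + fl / 2)
      chroms <- c(chroms, ch)
    }
    fs <- round(centers - fl / 2)
    fs <- pmin(pmax(fs, 0), gen[chroms] - fl)
    fe <- fs + fl
    rl <- config$read_length
    reads(chrom = c(chroms, chroms),
          start = c(fs, fe - rl),
          end = c(fs + rl, fe),
          strand = rep(c("+", "-"), each = n_frag))
  }), labels)

  structure(list(config = config, sites = sites, detected = detected,
                 peak_sets = peak_sets, read_sets = read_sets),
            class = "sim_truth")
}

#' Closed-form recovery probability under a consensus rule
#'
#' With per-replicate detection probability p and n replicates, the chance a
#' true site is recovered is a binomial tail: strict majority
#' P(X > n/2), absolute consensus p^n, any-replicate 1 - (1-p)^n. Requiring
#' absolute consensus therefore discards sites at a rate that grows with n —
#' the analytic form of the argument for the majority rule.
#'
#' @param p_detect per-replicate detection probability.
#' @param n_replicates number of replicates.
#' @param rule "majority", "common_all" or "any".
#' @return probability.
#' @export
expected_recovery <- function(p_detect, n_replicates,
                              rule = c("majority", "common_all", "any")) {
  rule <- match.arg(rule)
  stopifnot(p_detect >= 0, p_detect <= 1)
  switch(rule,
    majority = stats::pbinom(floor(n_replicates / 2), n_replicates,
                             p_detect, lower.tail = FALSE),
    common_all = p_detect^n_replicates,
    any = 1 - (1 - p_detect)^n_replicates)
}

#' Observed recovery of true sites under each rule
#'
#' Runs the grouping/classification pipeline on a simulated experiment and,
#' for each true site, takes the largest support among groups overlapping
#' it. A site is recovered under the majority rule when that support exceeds
#' n/2, under absolute consensus when it equals n.
#'
#' @param sim a `sim_truth`.
#' @param groups optional precomputed classified `peak_groups`; computed
#'   from `sim$peak_sets` when missing.
#' @return list: per-site `support`, and fractions `majority`, `common_all`,
#'   `any`.
#' @export
truth_recovery <- function(sim, groups = NULL) {
  stopifnot(inherits(sim, "sim_truth"))
  if (is.null(groups))
    groups <- classify_groups(group_peaks(sim$peak_sets))
  gdf <- groups$groups
  hit <- GenomicRanges::findOverlaps(as_gr(sim$sites), as_gr(gdf))
  sup <- integer(nrow(sim$sites))
  agg <- tapply(gdf$n_support[S4Vectors::subjectHits(hit)],
                S4Vectors::queryHits(hit), max)
  sup[as.integer(names(agg))] <- agg
  n <- groups$n_replicates
  list(support = sup,
       majority = mean(sup > n / 2),
       common_all = mean(sup == n),
       any = mean(sup >= 1))
}

#' Write a simulated experiment to disk
#'
#' Emits the file set the rest of the toolkit reads back: truth sites BED,
#' per-replicate peak BED6 and read BED6, a chromosome-sizes TSV, and a toy
#' GFF3 gene annotation (random non-overlapping genes) for the
#' feature-based modules.
#'
#' @param sim a `sim_truth`.
#' @param dir output directory (created if needed).
#' @param n_genes genes in the toy annotation (default 20).
#' @return invisibly, the named list of written paths.
#' @export
write_simulation <- function(sim, dir, n_genes = 20) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gen <- chrom_sizes(sim$config$genome)
  paths <- list()
  truth <- sim$sites
  truth$name <- truth$site_id
  paths$truth <- file.path(dir, "truth_sites.bed")
  write_regions(truth, paths$truth)
  paths$chrom_sizes <- file.path(dir, "genome.chrom.sizes")
  utils::write.table(data.frame(names(gen), format_bp(gen)),
                     paths$chrom_sizes, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  for (l in names(sim$peak_sets)) {
    paths[[paste0("peaks_", l)]] <- file.path(dir, paste0(l, ".peaks.bed"))
    write_regions(sim$peak_sets[[l]], paths[[paste0("peaks_", l)]])
    paths[[paste0("reads_", l)]] <- file.path(dir, paste0(l, ".reads.bed"))
    rr <- sim$read_sets[[l]]
    rr$name <- "."
    write_regions(rr, paths[[paste0("reads_", l)]])
  }
  ch <- names(gen)[1]
  w <- round(stats::runif(n_genes, 2000, 10000))
  g <- place_sites(n_genes, w, gen[[ch]])
  gff <- sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=simgene_%03d",
                 ch, g$start + 1, g$end,
                 sample(c("+", "-"), n_genes, replace = TRUE),
                 seq_len(n_genes))
  paths$gff <- file.path(dir, "genes.gff3")
  writeLines(c("##gff-version 3", gff), paths$gff)
  invisible(paths)
}
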