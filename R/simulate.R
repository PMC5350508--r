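#' Simulate a known-motif library
#'
#' Builds sharp consensus-based PWMs: the consensus base carries probability
#' 0.97 per position, the other bases 0.01 each, and the detection threshold
#' is set at `threshold_frac` of the maximum attainable log2-odds score
#' against a uniform background.  At the default 0.85 a single mismatch
#' (cost ~6.6 bits) already falls below threshold, so these motifs behave as
#' near-exact consensus detectors — a deterministic lower bound on
#' detectability for planted-truth benchmarks.
#'
#' @param n_motifs number of motifs.
#' @param lengths pool of consensus lengths to draw from.
#' @param seed integer seed.
#' @param threshold_frac detection threshold as a fraction of the maximum
#'   score.
#' @return List of [motif_pwm()] objects with ids `"motif_01"`, ...
#' @export
simulate_motif_library <- function(n_motifs = 50L, lengths = 8:12,
                                   seed = 1L, threshold_frac = 0.85) {
    set.seed(as.integer(seed))
    lapply(seq_len(n_motifs), function(i) {
        L <- sample(lengths, 1L)
        consensus <- paste(sample(BASES, L, replace = TRUE), collapse = "")
        mat <- matrix(0.01, L, 4L)
        mat[cbind(seq_len(L), match(strsplit(consensus, "")[[1L]], BASES))] <- 0.97
        max_score <- L * log2(0.97 / 0.25)
        motif_pwm(sprintf("motif_%02d", i), mat,
                  detection_threshold = threshold_frac * max_score,
                  consensus = consensus)
    })
}

#' Configuration for the peak-sequence simulator
#'
#' @param peaks_per_state peaks called in each of the three states.
#' @param peak_length peak width in bp.
#' @param common_fraction fraction of each state's peaks belonging to the
#'   consensus block shared identically by all states (default 0.45,
#'   matching the roughly balanced common-versus-unique split seen in
#'   three-state H3K27ac comparisons).
#' @param plant_rates data.frame with columns `state`, `motif_id`, `rate`:
#'   the fraction of that state's unique peaks receiving one exact-consensus
#'   insertion of that motif.
#' @param background_base_frequencies background composition for the i.i.d.
#'   sequence generator.
#' @param state_labels labels of the three states.
#' @param seed integer seed.
#' @return List of class `PeakSimConfig`.
#' @export
peak_sim_config <- function(peaks_per_state = 500L, peak_length = 200L,
                            common_fraction = 0.45,
                            plant_rates = NULL,
                            background_base_frequencies = rep(0.25, 4),
                            state_labels = c("MHCII_lo_unstim",
                                             "MHCII_hi_unstim",
                                             "MHCII_hi_LPS"),
                            seed = 1L) {
    stopifnot(common_fraction >= 0, common_fraction <= 1,
              length(state_labels) == 3L,
              abs(sum(background_base_frequencies) - 1) < 1e-6)
    if (is.null(plant_rates))
        plant_rates <- data.frame(state = character(), motif_id = character(),
                                  rate = numeric(), stringsAsFactors = FALSE)
    stopifnot(all(plant_rates$rate >= 0 & plant_rates$rate <= 1),
              all(plant_rates$state %in% state_labels))
    structure(list(peaks_per_state = as.integer(peaks_per_state),
                   peak_length = as.integer(peak_length),
                   common_fraction = common_fraction,
                   plant_rates = plant_rates,
                   background_base_frequencies = background_base_frequencies,
                   state_labels = state_labels,
                   seed = as.integer(seed)),
              class = "PeakSimConfig")
}

random_dna <- function(n, length, freqs = rep(0.25, 4)) {
    chars <- sample(BASES, n * length, replace = TRUE, prob = freqs)
    apply(matrix(chars, nrow = length), 2L, paste, collapse = "")
}

#' Generate peak sets and sequences with planted motif occurrences
#'
#' Emulates the three-state H3K27ac input: each state's peaks split into a
#' consensus block shared identically by all three states and a
#' state-unique, mutually disjoint block.  For every `(state, motif)` plant
#' rate `r`, exactly `round(r * n_unique)` of that state's unique peaks
#' receive one exact-consensus insertion at a random interior offset and
#' random strand; insertions within a peak never overlap each other or the
#' peak edges, so every planted site stays intact.  The truth table records
#' every insertion.  Deterministic given the config (which carries the
#' seed).
#'
#' @param cfg a [peak_sim_config()].
#' @param library motif library supplying the consensus strings; must cover
#'   every motif named in `cfg$plant_rates`.
#' @return List with `peak_sets` (per-state [peak_set()]), `sequences`
#'   (per-state named character vectors covering all of that state's
#'   peaks), `truth` (data.frame: state, peak_id, motif_id, offset, strand)
#'   and `unique_ids` (per-state ids of the unique peaks).
#' @export
gen_motif_peak_data <- function(cfg, library) {
    stopifnot(inherits(cfg, "PeakSimConfig"))
    lib_ids <- vapply(library, `[[`, "", "motif_id")
    unknown <- setdiff(cfg$plant_rates$motif_id, lib_ids)
    if (length(unknown))
        stop("plant rates name motifs absent from the library: ",
             paste(unknown, collapse = ", "))
    lens <- nchar(vapply(library, `[[`, "", "consensus"))
    if (any(lens[match(cfg$plant_rates$motif_id, lib_ids)] +
            2L > cfg$peak_length))
        stop("motif longer than peak_length - 2; cannot plant")
    set.seed(cfg$seed)
    n_common <- round(cfg$common_fraction * cfg$peaks_per_state)
    n_unique <- cfg$peaks_per_state - n_common
    slot_w <- cfg$peak_length + 100L
    # disjoint genomic slots: common block first, then one block per state
    slot_start <- function(i) (i - 1L) * slot_w
    common_iv <- data.frame(
        chrom = "chr1",
        start = slot_start(seq_len(n_common)),
        end = slot_start(seq_len(n_common)) + cfg$peak_length,
        name = sprintf("common_%04d", seq_len(n_common)),
        stringsAsFactors = FALSE)
    common_seq <- setNames(
        random_dna(n_common, cfg$peak_length,
                   cfg$background_base_frequencies),
        common_iv$name)
    peak_sets <- list(); sequences <- list(); unique_ids <- list()
    truth <- list()
    for (si in 1:3) {
        state <- cfg$state_labels[si]
        offset_slots <- n_common + (si - 1L) * n_unique
        ids <- sprintf("%s_uniq_%04d", state, seq_len(n_unique))
        uniq_iv <- data.frame(
            chrom = "chr1",
            start = slot_start(offset_slots + seq_len(n_unique)),
            end = slot_start(offset_slots + seq_len(n_unique)) +
                cfg$peak_length,
            name = ids, stringsAsFactors = FALSE)
        seqs <- setNames(random_dna(n_unique, cfg$peak_length,
                                    cfg$background_base_frequencies), ids)
        occupied <- setNames(vector("list", n_unique), ids)
        rates <- cfg$plant_rates[cfg$plant_rates$state == state, ,
                                 drop = FALSE]
        for (ri in seq_len(nrow(rates))) {
            motif <- library[[match(rates$motif_id[ri], lib_ids)]]
            L <- nchar(motif$consensus)
            n_ins <- round(rates$rate[ri] * n_unique)
            if (n_ins == 0L) next
            chosen <- sample(ids, n_ins)
            for (id in chosen) {
                off <- pick_free_offset(occupied[[id]], cfg$peak_length, L)
                if (is.na(off)) next  # peak saturated; realistically unreachable
                strand <- sample(c("+", "-"), 1L)
                ins <- if (strand == "+") motif$consensus else
                    reverse_complement(motif$consensus)
                substr(seqs[[id]], off + 1L, off + L) <- ins
                occupied[[id]] <- rbind(occupied[[id]], c(off, off + L))
                truth[[length(truth) + 1L]] <- data.frame(
                    state = state, peak_id = id,
                    motif_id = motif$motif_id, offset = off,
                    strand = strand, stringsAsFactors = FALSE)
            }
        }
        iv <- rbind(common_iv, uniq_iv)
        peak_sets[[state]] <- peak_set(iv, state)
        sequences[[state]] <- c(common_seq, seqs)
        unique_ids[[state]] <- ids
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
        data.frame(state = character(), peak_id = character(),
                   motif_id = character(), offset = integer(),
                   strand = character(), stringsAsFactors = FALSE)
    list(peak_sets = peak_sets, sequences = sequences, truth = truth,
         unique_ids = unique_ids)
}

# Uniform draw of a 0-based insertion offset in [1, peak_length - L - 1]
# avoiding previously occupied [start, end) stretches; NA when no room.
pick_free_offset <- function(occ, peak_length, L) {
    cand <- seq.int(1L, peak_length - L - 1L)
    if (!is.null(occ)) {
        for (i in seq_len(nrow(occ)))
            cand <- cand[cand + L <= occ[i, 1L] | cand >= occ[i, 2L]]
    }
    if (length(cand) == 0L) return(NA_integer_)
    cand[sample.int(length(cand), 1L)]
}

#' Configuration for the co-expression compendium simulator
#'
#' @param n_genes total genes.
#' @param n_populations populations (columns); >= 4 so correlation p-values
#'   are defined.
#' @param module_size genes in the seed-correlated module.
#' @param module_rho target Pearson correlation of module genes with the
#'   seed.
#' @param noise_sd scale of the independent noise component of module genes
#'   (1 leaves the expected correlation at `module_rho`).
#' @param seed integer seed.
#' @return List of class `CoexprSimConfig`.
#' @export
coexpr_sim_config <- function(n_genes = 5000L, n_populations = 27L,
                              module_size = 50L, module_rho = 0.9,
                              noise_sd = 1, seed = 1L) {
    stopifnot(module_size < n_genes, abs(module_rho) <= 1, noise_sd >= 0)
    if (n_populations < 4L)
        stop("need >= 4 populations (correlation p-value undefined below ",
             "3 degrees of freedom)")
    structure(list(n_genes = as.integer(n_genes),
                   n_populations = as.integer(n_populations),
                   module_size = as.integer(module_size),
                   module_rho = module_rho, noise_sd = noise_sd,
                   seed = as.integer(seed)),
              class = "CoexprSimConfig")
}

#' Generate a compendium with a planted seed-correlated module
#'
#' The seed gene (`"seed_gene"`) is standard normal across populations; each
#' module gene is `rho * seed + sqrt(1 - rho^2) * noise_sd * eps` with
#' independent standard-normal `eps` (so at `noise_sd = 1` its expected
#' correlation with the seed is exactly `rho`, and at `noise_sd = 0,
#' rho = 1` it duplicates the seed); the remaining genes are independent
#' standard normals.  Deterministic given the config.
#'
#' @param cfg a [coexpr_sim_config()].
#' @return List with `expr` ([expression_matrix()] of population means,
#'   including the seed gene) and `truth` (module gene ids).
#' @export
gen_coexpression_data <- function(cfg) {
    stopifnot(inherits(cfg, "CoexprSimConfig"))
    set.seed(cfg$seed)
    pops <- sprintf("pop_%02d", seq_len(cfg$n_populations))
    seed_profile <- rnorm(cfg$n_populations)
    module_ids <- sprintf("module_gene_%04d", seq_len(cfg$module_size))
    null_ids <- sprintf("null_gene_%04d",
                        seq_len(cfg$n_genes - cfg$module_size - 1L))
    module <- t(vapply(module_ids, function(g)
        cfg$module_rho * seed_profile +
            sqrt(1 - cfg$module_rho^2) * cfg$noise_sd *
            rnorm(cfg$n_populations),
        numeric(cfg$n_populations)))
    nulls <- matrix(rnorm(length(null_ids) * cfg$n_populations),
                    nrow = length(null_ids),
                    dimnames = list(null_ids, pops))
    values <- rbind(matrix(seed_profile, 1L,
                           dimnames = list("seed_gene", pops)),
                    module, nulls)
    colnames(values) <- pops
    meta <- data.frame(sample_id = pops, population = pops,
                       stringsAsFactors = FALSE)
    list(expr = expression_matrix(values, meta), truth = module_ids)
}

#' Configuration for the LPS time-course simulator
#'
#' @param archetypes k x 4 matrix of mean log2 offsets (relative to
#'   baseline) at t = 0, 1, 6, 24 h; defaults to
#'   [default_kinetic_archetypes()].
#' @param genes_per_archetype genes per archetype (recycled to k).
#' @param n_null_genes unresponsive genes with a constant mean.
#' @param replicate_sd Gaussian replicate noise SD (log2 units).
#' @param n_reps replicates per time point (default 3).
#' @param seed integer seed.
#' @return List of class `TimecourseSimConfig`.
#' @export
timecourse_sim_config <- function(archetypes = default_kinetic_archetypes(),
                                  genes_per_archetype = 50L,
                                  n_null_genes = 0L,
                                  replicate_sd = 0.25,
                                  n_reps = 3L, seed = 1L) {
    archetypes <- as.matrix(archetypes)
    if (ncol(archetypes) != 4L)
        stop("archetypes must have 4 columns (t = 0, 1, 6, 24 h)")
    if (nrow(archetypes) < 1L) stop("need at least one archetype")
    genes_per_archetype <- rep_len(as.integer(genes_per_archetype),
                                   nrow(archetypes))
    structure(list(archetypes = archetypes,
                   genes_per_archetype = genes_per_archetype,
                   n_null_genes = as.integer(n_null_genes),
                   replicate_sd = replicate_sd,
                   n_reps = as.integer(n_reps),
                   seed = as.integer(seed)),
              class = "TimecourseSimConfig")
}

#' Twelve default kinetic archetypes
#'
#' Mean log2 offsets (relative to the gene's baseline) at t = 0, 1, 6, 24 h
#' emulating the shapes seen after LPS stimulation: early/mid/late transient
#' induction, fast/delayed/late sustained induction, gradual induction, and
#' their repression mirrors, at an amplitude of 2 log2 units.
#'
#' @return 12 x 4 numeric matrix, rows `arch_01` ... `arch_12`.
#' @export
default_kinetic_archetypes <- function() {
    m <- rbind(
        c(0,  2,  2,  2),   # fast sustained induction
        c(0,  0,  2,  2),   # delayed sustained induction
        c(0,  0,  0,  2),   # late induction
        c(0,  2,  0,  0),   # early transient (inflammatory-like)
        c(0,  0,  2,  0),   # mid transient (antiviral-like)
        c(0,  2,  2,  0),   # broad transient
        c(0,  0.7, 1.3, 2), # gradual induction
        c(0, -2, -2, -2),   # fast sustained repression
        c(0,  0, -2, -2),   # delayed repression
        c(0,  0,  0, -2),   # late repression
        c(0, -2,  0,  0),   # transient repression
        c(0, -0.7, -1.3, -2)) # gradual repression
    dimnames(m) <- list(sprintf("arch_%02d", 1:12), c("0", "1", "6", "24"))
    m
}

#' Generate an LPS-like stimulation time course with planted kinetics
#'
#' Each responsive gene gets a baseline (N(6, 1) log2 intensity) plus its
#' archetype's mean offset at each time point, with independent
#' `N(0, replicate_sd^2)` replicate noise; null genes keep a constant mean.
#' Deterministic given the config.
#'
#' @param cfg a [timecourse_sim_config()].
#' @return List with `expr` ([expression_matrix()], 4 x n_reps samples) and
#'   `truth` (named character vector, gene -> archetype id or `"null"`).
#' @export
gen_timecourse_data <- function(cfg) {
    stopifnot(inherits(cfg, "TimecourseSimConfig"))
    set.seed(cfg$seed)
    k <- nrow(cfg$archetypes)
    arch_ids <- rownames(cfg$archetypes)
    if (is.null(arch_ids)) arch_ids <- sprintf("arch_%02d", seq_len(k))
    gene_arch <- rep(arch_ids, cfg$genes_per_archetype)
    genes <- c(sprintf("resp_gene_%05d", seq_along(gene_arch)),
               if (cfg$n_null_genes > 0L)
                   sprintf("null_gene_%05d", seq_len(cfg$n_null_genes)))
    truth <- setNames(c(gene_arch, rep("null", cfg$n_null_genes)), genes)
    samples <- as.vector(outer(TIMEPOINTS_H, seq_len(cfg$n_reps),
                               function(t, r) sprintf("t%g_rep%d", t, r)))
    time_h <- rep(TIMEPOINTS_H, times = cfg$n_reps)
    # sample order: all 4 time points for rep1, then rep2, ...
    baseline <- rnorm(length(genes), mean = 6, sd = 1)
    mean_by_time <- matrix(0, length(genes), 4L)
    resp <- truth != "null"
    mean_by_time[resp, ] <- cfg$archetypes[match(truth[resp], arch_ids), ,
                                           drop = FALSE]
    mean_by_time <- mean_by_time + baseline
    tp_idx <- match(time_h, TIMEPOINTS_H)
    values <- mean_by_time[, tp_idx, drop = FALSE] +
        matrix(rnorm(length(genes) * length(samples), sd = cfg$replicate_sd),
               nrow = length(genes))
    dimnames(values) <- list(genes, samples)
    meta <- data.frame(sample_id = samples, time_h = time_h,
                       replicate = rep(seq_len(cfg$n_reps),
                                       each = length(TIMEPOINTS_H)),
                       stringsAsFactors = FALSE)
    list(expr = expression_matrix(values, meta), truth = truth)
}

#' Assemble the three-state differential-motif benchmark
#'
#' The full synthetic scenario for exercising the differential-enrichment
#' statistic end to end: a simulated motif library; every motif planted in
#' each state's unique peaks at a state-INDEPENDENT base rate drawn once
#' per motif from `U(0, base_rate_max)` (regulatory regions are motif-dense,
#' and shared motif content is what anchors the strong cross-state
#' enrichment trend the regression fits); and one focal motif planted
#' differentially — `focal_rate_lps` in the LPS-unique peaks versus
#' `focal_rate_other` in the other two states' unique peaks.
#'
#' @param n_motifs library size (default 50).
#' @param peaks_per_state peaks per state (default 500).
#' @param peak_length peak width (default 200 bp).
#' @param focal_rate_lps,focal_rate_other plant rates of the focal motif
#'   (defaults 0.30 and 0.05).
#' @param base_rate_max upper bound of the per-motif base plant rate
#'   (default 0.30).
#' @param seed integer seed.
#' @return List with `library`, `focal_motif`, `data`
#'   (from [gen_motif_peak_data()]) and `config`.
#' @export
simulate_motif_benchmark <- function(n_motifs = 50L, peaks_per_state = 500L,
                                     peak_length = 200L,
                                     focal_rate_lps = 0.30,
                                     focal_rate_other = 0.05,
                                     base_rate_max = 0.30,
                                     seed = 1L) {
    seed <- as.integer(seed)
    library <- simulate_motif_library(n_motifs, seed = seed)
    set.seed(seed + 1000L)
    ids <- vapply(library, `[[`, "", "motif_id")
    base_rates <- runif(n_motifs, 0, base_rate_max)
    focal <- ids[sample.int(n_motifs, 1L)]
    states <- c("MHCII_lo_unstim", "MHCII_hi_unstim", "MHCII_hi_LPS")
    rates <- expand.grid(state = states, motif_id = ids,
                         stringsAsFactors = FALSE)
    rates$rate <- base_rates[match(rates$motif_id, ids)]
    rates$rate[rates$motif_id == focal] <-
        ifelse(rates$state[rates$motif_id == focal] == "MHCII_hi_LPS",
               focal_rate_lps, focal_rate_other)
    cfg <- peak_sim_config(peaks_per_state = peaks_per_state,
                           peak_length = peak_length,
                           plant_rates = rates, seed = seed + 2000L)
    list(library = library, focal_motif = focal,
         data = gen_motif_peak_data(cfg, library), config = cfg)
}
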