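#' Define a class plan for the repeat simulator
#'
#' A class plan describes the structural signal that marks a simulated TE
#' family, mirroring the biology the classifier exploits: terminal direct
#' repeats (LTR-like), reverse-complement-matched terminal inverted repeats
#' (TIR-like), fixed termini strings (e.g. the 5'-CACTA...TAGTG-3' ends of
#' CACTA elements), 3' homopolymer tails (poly(A) for L1-like LINEs, poly(T)
#' for SINE2-like Pol III transcripts), global k-mer composition bias, and
#' motifs planted away from the termini (decoys whose composition matches a
#' terminal-motif class without its terminal structure).
#'
#' @param n Number of sequences to simulate for the class.
#' @param ltr_len Length of a direct terminal repeat planted at both ends
#'   (0 = none).
#' @param tir_len Length of a terminal inverted repeat: motif at the 5' end,
#'   its reverse complement at the 3' end (0 = none).
#' @param terminal_motif Fixed motif string for `ltr_len`/`tir_len` planting;
#'   when `NULL` a family consensus motif is drawn deterministically from the
#'   simulation seed and class label.
#' @param head,tail Fixed strings forced onto the extreme 5'/3' ends.
#' @param polya,polyt Length of a 3' poly(A)/poly(T) tail (0 = none).
#' @param bias_kmers Character vector of words whose frequency is raised.
#' @param bias_fold Target fold-enrichment of each biased word over its
#'   background expectation (default 3).
#' @param bias_region `"anywhere"` or `"interior"` (keep extra copies out of
#'   the terminal margin so the bias is invisible to the local branch).
#' @param interior_motifs Character vector of motif strings each planted once
#'   at a random interior position.
#' @return A list with class `te_class_plan`.
#' @export
class_plan <- function(n, ltr_len = 0, tir_len = 0, terminal_motif = NULL,
                       head = NULL, tail = NULL, polya = 0, polyt = 0,
                       bias_kmers = NULL, bias_fold = 3,
                       bias_region = c("anywhere", "interior"),
                       interior_motifs = NULL) {
  stopifnot(n >= 0, ltr_len >= 0, tir_len >= 0, polya >= 0, polyt >= 0,
            bias_fold >= 1)
  structure(list(n = n, ltr_len = ltr_len, tir_len = tir_len,
                 terminal_motif = terminal_motif, head = head, tail = tail,
                 polya = polya, polyt = polyt,
                 bias_kmers = bias_kmers, bias_fold = bias_fold,
                 bias_region = match.arg(bias_region),
                 interior_motifs = interior_motifs),
            class = "te_class_plan")
}

#' Define a full simulation
#'
#' @param classes Named list of [class_plan()]s; names are taxonomy labels.
#' @param length_range Uniform sequence-length range in bp (min >= 80 so all
#'   simulated records pass preprocessing).
#' @param base_comp Background base probabilities (A, C, G, T).
#' @param mutation_rate Per-base substitution probability applied to planted
#'   motifs (in `[0, 1)`; background is already random).
#' @param interior_margin Terminal margin (bp) kept free of interior-planted
#'   material when `bias_region = "interior"` or for `interior_motifs`
#'   (default 100, i.e. the local branch's view at L = 100).
#' @param species Species tag written into headers (default "SIM").
#' @param seed Integer master seed; every sequence's seed derives from it.
#' @return A `te_sim_spec` list.
#' @export
simulation_spec <- function(classes, length_range = c(300, 1500),
                            base_comp = c(A = .25, C = .25, G = .25, T = .25),
                            mutation_rate = 0.05, interior_margin = 100,
                            species = "SIM", seed = 1) {
  stopifnot(is.list(classes), length(classes) > 0, !is.null(names(classes)),
            length(length_range) == 2, length_range[1] >= 80,
            length_range[1] <= length_range[2],
            length(base_comp) == 4, all(base_comp >= 0), sum(base_comp) > 0,
            mutation_rate >= 0, mutation_rate < 1)
  for (cl in classes) stopifnot(inherits(cl, "te_class_plan"))
  structure(list(classes = classes, length_range = length_range,
                 base_comp = base_comp / sum(base_comp),
                 mutation_rate = mutation_rate,
                 interior_margin = interior_margin,
                 species = species, seed = seed),
            class = "te_sim_spec")
}

label_seed <- function(seed, label, i = 0L) {
  (as.numeric(seed) * 7919 + sum(utf8ToInt(label)) * 104729 + i * 65537) %%
    2147483647
}

family_motif <- function(spec, label, len) {
  old <- .Random.seed_safe()
  set.seed(label_seed(spec$seed, label))
  on.exit(.Random.seed_restore(old), add = TRUE)
  paste(sample(BASES, len, replace = TRUE), collapse = "")
}

draw_length <- function(range) {
  if (range[1] == range[2]) range[1] else sample(range[1]:range[2], 1)
}

plant <- function(chars, motif, at) {
  m <- strsplit(motif, "", fixed = TRUE)[[1]]
  chars[at:(at + length(m) - 1)] <- m
  chars
}

#' Simulate one labelled TE-like sequence
#'
#' Draws a background sequence from the spec's base composition and plants
#' the class's motif plan (bias words, interior motifs, terminal repeats,
#' fixed termini, homopolymer tails, in that order), then applies point
#' mutations to the planted positions at the spec's mutation rate.
#' Deterministic for a fixed `(class_label, spec, seed)`.
#'
#' @param class_label Name of a class in `spec$classes`.
#' @param spec A `te_sim_spec`.
#' @param seed Integer seed for this sequence.
#' @return One-row tibble: `id`, `label`, `species`, `seq`.
#' @export
simulate_te <- function(class_label, spec, seed) {
  stopifnot(inherits(spec, "te_sim_spec"))
  plan <- spec$classes[[class_label]]
  if (is.null(plan)) stop("class not in spec: ", class_label, call. = FALSE)

  old <- .Random.seed_safe()
  set.seed(seed %% 2147483647)
  on.exit(.Random.seed_restore(old), add = TRUE)

  len <- draw_length(spec$length_range)
  term_need <- max(plan$ltr_len, plan$tir_len) + nchar(plan$head %||% "") +
    nchar(plan$tail %||% "") + plan$polya + plan$polyt
  if (2 * term_need + 20 > len) {
    stop("length ", len, " too short to host planted elements of class ",
         class_label, call. = FALSE)
  }
  chars <- sample(BASES, len, replace = TRUE, prob = spec$base_comp)
  planted <- logical(len)
  mark <- function(at, w) planted[at:(at + w - 1)] <<- TRUE

  interior_range <- function(w) {
    lo <- spec$interior_margin + 1
    hi <- len - spec$interior_margin - w + 1
    if (hi < lo) stop("sequence too short for interior planting", call. = FALSE)
    c(lo, hi)
  }

  # composition bias: extra copies of each designated word, enough to lift
  # its expected frequency to ~bias_fold x background
  for (w in plan$bias_kmers %||% character()) {
    k <- nchar(w)
    extra <- max(1, round((plan$bias_fold - 1) * (len - k + 1) / 4^k))
    rg <- if (plan$bias_region == "interior") interior_range(k) else c(1, len - k + 1)
    for (pos in sample(rg[1]:rg[2], extra, replace = TRUE)) {
      chars <- plant(chars, w, pos); mark(pos, k)
    }
  }
  for (m in plan$interior_motifs %||% character()) {
    rg <- interior_range(nchar(m))
    pos <- sample(rg[1]:rg[2], 1)
    chars <- plant(chars, m, pos); mark(pos, nchar(m))
  }
  if (plan$tir_len > 0) {
    M <- plan$terminal_motif %||% family_motif(spec, class_label, plan$tir_len)
    chars <- plant(chars, M, 1); mark(1, plan$tir_len)
    rc <- reverse_complement(M)
    chars <- plant(chars, rc, len - plan$tir_len + 1)
    mark(len - plan$tir_len + 1, plan$tir_len)
  }
  if (plan$ltr_len > 0) {
    M <- plan$terminal_motif %||% family_motif(spec, class_label, plan$ltr_len)
    chars <- plant(chars, M, 1); mark(1, plan$ltr_len)
    chars <- plant(chars, M, len - plan$ltr_len + 1)
    mark(len - plan$ltr_len + 1, plan$ltr_len)
  }
  if (plan$polya > 0) {
    chars <- plant(chars, strrep("A", plan$polya), len - plan$polya + 1)
    mark(len - plan$polya + 1, plan$polya)
  }
  if (plan$polyt > 0) {
    chars <- plant(chars, strrep("T", plan$polyt), len - plan$polyt + 1)
    mark(len - plan$polyt + 1, plan$polyt)
  }
  if (!is.null(plan$head)) {
    chars <- plant(chars, plan$head, 1); mark(1, nchar(plan$head))
  }
  if (!is.null(plan$tail)) {
    chars <- plant(chars, plan$tail, len - nchar(plan$tail) + 1)
    mark(len - nchar(plan$tail) + 1, nchar(plan$tail))
  }
  if (spec$mutation_rate > 0 && any(planted)) {
    hit <- which(planted & stats::runif(len) < spec$mutation_rate)
    for (i in hit) chars[i] <- sample(setdiff(BASES, chars[i]), 1)
  }
  tibble::tibble(id = paste0(gsub("[^A-Za-z0-9]", "", class_label), "_s", seed),
                 label = class_label, species = spec$species,
                 seq = paste(chars, collapse = ""))
}

#' Simulate a labelled repeat library
#'
#' One record per requested sequence across all classes of the spec, with
#' deterministic per-sequence seeds derived from the spec's master seed.
#' Headers follow the `ID|TE_type|Species_ID` nomenclature when written to
#' FASTA.
#'
#' @param spec A `te_sim_spec`.
#' @param tax Optional `te_taxonomy`; when supplied every class label must
#'   resolve in it.
#' @param fasta,truth Optional output paths for the FASTA file (80-column
#'   wrapped) and the truth table TSV (`id`, `leaf_label`, `species`).
#' @return Tibble of records (`id`, `label`, `species`, `seq`).
#' @export
simulate_dataset <- function(spec, tax = NULL, fasta = NULL, truth = NULL) {
  stopifnot(inherits(spec, "te_sim_spec"))
  if (!is.null(tax)) {
    for (lb in names(spec$classes)) resolve_label(tax, lb)
  }
  recs <- purrr::map_dfr(names(spec$classes), function(lb) {
    n <- spec$classes[[lb]]$n
    if (n == 0) return(tibble::tibble())
    purrr::map_dfr(seq_len(n), function(i) {
      r <- simulate_te(lb, spec, seed = label_seed(spec$seed, lb, i))
      r$id <- sprintf("%s_%04d", gsub("[^A-Za-z0-9]", "", lb), i)
      r
    })
  })
  if (!is.null(fasta)) write_fasta(recs, fasta)
  if (!is.null(truth)) {
    utils::write.table(
      data.frame(id = recs$id, leaf_label = recs$label, species = recs$species),
      truth, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  recs
}

#' Simulate a non-TE decoy sequence
#'
#' `"coding-like"` sequences are codon-structured: an ATG start, in-frame
#' sense codons drawn from a biased codon-usage table, and a stop codon.
#' `"tandem-repeat"` sequences repeat a random unit to the target length with
#' per-copy point mutations at the spec's mutation rate. Both are the
#' negative classes of a TE / CDS / TR discrimination task.
#'
#' @param kind `"coding-like"` or `"tandem-repeat"`.
#' @param spec A `te_sim_spec` (length range, composition, mutation rate).
#' @param seed Integer seed.
#' @param unit_len Tandem-repeat unit length (default 6); must not exceed the
#'   drawn sequence length.
#' @return One-row tibble: `id`, `label` (`"CDS"` or `"TR"`), `species`,
#'   `seq`.
#' @export
simulate_non_te <- function(kind = c("coding-like", "tandem-repeat"), spec,
                            seed, unit_len = 6) {
  kind <- match.arg(kind)
  stopifnot(inherits(spec, "te_sim_spec"))
  old <- .Random.seed_safe()
  set.seed(seed %% 2147483647)
  on.exit(.Random.seed_restore(old), add = TRUE)
  len <- draw_length(spec$length_range)
  if (kind == "coding-like") {
    len <- len - len %% 3
    stops <- c("TAA", "TAG", "TGA")
    sense <- setdiff(as.vector(outer(as.vector(outer(BASES, BASES, paste0)),
                                     BASES, paste0)), stops)
    # fixed mild codon-usage bias: G/C-ending codons preferred, as in many
    # highly expressed genes
    wt <- ifelse(substr(sense, 3, 3) %in% c("G", "C"), 3, 1)
    body <- sample(sense, len / 3 - 2, replace = TRUE, prob = wt)
    seqs <- paste0("ATG", paste(body, collapse = ""), sample(stops, 1))
    lab <- "CDS"
  } else {
    if (unit_len > len) {
      stop("tandem unit length ", unit_len, " exceeds sequence length ", len,
           call. = FALSE)
    }
    unit <- sample(BASES, unit_len, replace = TRUE, prob = spec$base_comp)
    copies <- ceiling(len / unit_len)
    mat <- replicate(copies, {
      u <- unit
      if (spec$mutation_rate > 0) {
        hit <- which(stats::runif(unit_len) < spec$mutation_rate)
        for (i in hit) u[i] <- sample(setdiff(BASES, u[i]), 1)
      }
      u
    })
    seqs <- substr(paste(as.vector(mat), collapse = ""), 1, len)
    lab <- "TR"
  }
  tibble::tibble(id = paste0(lab, "_s", seed), label = lab,
                 species = spec$species, seq = seqs)
}
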