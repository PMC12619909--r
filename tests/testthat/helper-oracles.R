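# Independent oracles used across tests. All deliberately naive: they trade
# speed for obviousness and share no code with the implementation.

# dictionary k-mer counter: enumerate every window as a substring
naive_kmer_count <- function(seq, k) {
  words <- hierTE:::kmer_words(k)
  counts <- stats::setNames(numeric(length(words)), words)
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n >= k) {
    for (i in 1:(n - k + 1)) {
      w <- substr(seq, i, i + k - 1)
      if (!grepl("[^ACGT]", w)) counts[w] <- counts[w] + 1
    }
  }
  counts
}

# random nucleotide string, optionally with ambiguous bases mixed in
random_seq <- function(len, ambig_frac = 0) {
  alph <- c("A", "C", "G", "T")
  s <- sample(alph, len, replace = TRUE)
  if (ambig_frac > 0) {
    n_amb <- floor(len * ambig_frac)
    if (n_amb > 0) s[sample(len, n_amb)] <- "N"
  }
  paste(s, collapse = "")
}

# recursive re-application of the stopping rule, independent of
# predict_topdown's loop: probs_of(node, id) -> named child probabilities
oracle_topdown <- function(tax, probs_of, id, threshold) {
  path <- tax$root
  repeat {
    node <- path[length(path)]
    kids <- taxonomy_children(tax, node)
    if (length(kids) == 0) break
    if (length(kids) == 1) { path <- c(path, kids); next }
    p <- probs_of(node, id)
    if (max(p) < threshold) break
    path <- c(path, sort(names(p)[p == max(p)])[1])
  }
  path
}

# uniformly random rooted tree over n labelled nodes (node i's parent is a
# uniform draw among earlier nodes)
random_taxonomy <- function(n_nodes, seed) {
  set.seed(seed)
  labels <- paste0("n", seq_len(n_nodes))
  parent <- c(NA, labels[vapply(2:n_nodes, function(i) sample(i - 1, 1), 1L)])
  cfg <- split(labels[-1], factor(parent[-1], levels = unique(parent[-1])))
  load_taxonomy(cfg)
}

# a random probability table over every multi-child node of a taxonomy
random_prob_table <- function(tax, ids, seed) {
  set.seed(seed)
  tab <- list()
  for (node in parent_nodes(tax)) {
    kids <- taxonomy_children(tax, node)
    m <- matrix(stats::rexp(length(ids) * length(kids)), length(ids))
    m <- m / rowSums(m)
    dimnames(m) <- list(ids, kids)
    tab[[node]] <- m
  }
  tab
}

# reduced-scale simulation scenarios shared by model-level tests and the
# acceptance suite: two classes separable only by terminal motif placement
# (same motif content at the termini vs deep inside the sequence), and two
# separable only by which 7-mer set is enriched away from both ends
terminal_contrast_spec <- function(seed) {
  M <- "ACGGTTCAGATTACCGGATAGCTTAGGCAT"
  simulation_spec(
    list(TIRlike = class_plan(n = 200, tir_len = 30, terminal_motif = M),
         INTlike = class_plan(n = 200,
                              interior_motifs = c(M, reverse_complement(M)))),
    length_range = c(300, 700), mutation_rate = 0.02,
    interior_margin = 100, seed = seed)
}

bias_contrast_spec <- function(seed) {
  simulation_spec(
    list(BiasA = class_plan(n = 200, bias_fold = 3, bias_region = "interior",
                            bias_kmers = c("ACGTACG", "GGATCCA", "TTGACGA",
                                           "CATCATG", "AGGCTAA", "TCTCGAC",
                                           "GTTAGGC", "CCAATGT")),
         BiasB = class_plan(n = 200, bias_fold = 3, bias_region = "interior",
                            bias_kmers = c("TGCATGC", "AACCGTT", "GAGATAG",
                                           "CTTGGAC", "TATACGC", "GCCTAAG",
                                           "ATGGTCA", "CGACTTG"))),
    length_range = c(300, 700), mutation_rate = 0.02,
    interior_margin = 100, seed = seed)
}

# desk-scale architecture + training settings used wherever a real model is
# trained in the tests
desk_build_args <- function() {
  list(k = 5, L = 100, conv_channels = c(8, 16, 32), gru_units = c(16, 8),
       dense_units = 32, dropout = 0.3, lr = 1e-3)
}

desk_train_args <- function(epochs = 30) {
  list(epochs = epochs, batch_size = 8, validation_split = 0.15,
       patience = 999)
}

train_eval_mcc <- function(spec, branches, seed, epochs = 30,
                           test_frac = 0.10) {
  recs <- simulate_dataset(spec)
  recs$class <- recs$label
  sp <- stratified_split(recs, test_frac = test_frac, seed = seed)
  tr <- featurize(sp$train, k = 5, L = 100)
  te <- featurize(sp$test, k = 5, L = 100)
  ba <- desk_build_args()
  mdl <- build_node_classifier("node", sort(unique(recs$label)),
                               k = ba$k, L = ba$L, seed = seed,
                               branches = branches,
                               conv_channels = ba$conv_channels,
                               gru_units = ba$gru_units,
                               dense_units = ba$dense_units,
                               dropout = ba$dropout, lr = ba$lr)
  mdl <- do.call(train_node_classifier,
                 c(list(model = mdl, records = tr, seed = seed),
                   desk_train_args(epochs)))
  pp <- predict_proba(mdl, te)
  pred <- mdl$child_labels[max.col(as.matrix(pp[mdl$child_labels]),
                                   ties.method = "first")]
  glance(flat_metrics(te$class, pred, mdl$child_labels))$mcc
}

# three-level pipeline scenario: the root splits on terminal structure, the
# retro-like subtree on composition bias, the DNA-like subtree on distinct
# inverted-repeat motifs
pipeline_taxonomy <- function() {
  load_taxonomy(list(TE = c("ClassI", "ClassII"),
                     ClassI = c("CopiaX", "GypsyX"),
                     ClassII = c("hATX", "CACTAX")))
}

pipeline_spec <- function(seed, n_per_class = 150) {
  MI <- "GATTACCGGATAGCTTAGGCATCCGATTAC"
  MC <- "TTGACGGCATTACAGGCTAACCTGATCCAG"
  MD <- "CACTACCTGGTAAGGCCATTGCAACTGGAT"
  bias_a <- c("ACGTACG", "GGATCCA", "TTGACGA", "CATCATG",
              "AGGCTAA", "TCTCGAC", "GTTAGGC", "CCAATGT")
  bias_b <- c("TGCATGC", "AACCGTT", "GAGATAG", "CTTGGAC",
              "TATACGC", "GCCTAAG", "ATGGTCA", "CGACTTG")
  simulation_spec(
    list(CopiaX = class_plan(n = n_per_class, ltr_len = 30,
                             terminal_motif = MI, bias_kmers = bias_a,
                             bias_fold = 3, bias_region = "interior"),
         GypsyX = class_plan(n = n_per_class, ltr_len = 30,
                             terminal_motif = MI, bias_kmers = bias_b,
                             bias_fold = 3, bias_region = "interior"),
         hATX = class_plan(n = n_per_class, tir_len = 30,
                           terminal_motif = MC),
         CACTAX = class_plan(n = n_per_class, tir_len = 30,
                             terminal_motif = MD)),
    length_range = c(300, 700), mutation_rate = 0.02,
    interior_margin = 100, seed = seed)
}

train_pipeline <- function(seed, epochs = 15) {
  tax <- pipeline_taxonomy()
  recs <- simulate_dataset(pipeline_spec(seed), tax = tax)
  sp <- stratified_split(recs, test_frac = 0.10, seed = seed)
  tr <- featurize(sp$train, k = 5, L = 100)
  te <- featurize(sp$test, k = 5, L = 100)
  nd <- build_node_datasets(tr, tax)
  ba <- desk_build_args()
  clfs <- list()
  for (p in parent_nodes(tax)) {
    sub <- nd[nd$parent == p, ]
    m <- build_node_classifier(p, sort(unique(sub$class)), k = ba$k,
                               L = ba$L, seed = seed,
                               conv_channels = ba$conv_channels,
                               gru_units = ba$gru_units,
                               dense_units = ba$dense_units,
                               dropout = ba$dropout, lr = ba$lr)
    clfs[[p]] <- do.call(train_node_classifier,
                         c(list(model = m, records = sub, seed = seed),
                           desk_train_args(epochs)))
  }
  list(tax = tax, classifiers = clfs, test = te,
       truth = stats::setNames(te$label, te$id))
}
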