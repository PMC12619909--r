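#' Read a repeat library from FASTA
#'
#' Headers following the `ID|TE_type|Species_ID` nomenclature are split into
#' the id, label and species fields (any further `|`-separated fields are
#' preserved verbatim in `extra`); headers without pipes yield records with
#' an absent (`NA`) label and a warning. Sequences are upper-cased. CRLF and
#' LF files parse identically.
#'
#' @param path FASTA file.
#' @return Tibble with `id`, `label`, `species`, `extra`, `seq`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0) {
    warning("empty FASTA file: ", path)
    return(tibble::tibble(id = character(), label = character(),
                          species = character(), extra = character(),
                          seq = character()))
  }
  headers <- trimws(names(set))
  parts <- strsplit(headers, "|", fixed = TRUE)
  id <- vapply(parts, `[[`, "", 1)
  if (anyDuplicated(id)) {
    stop("duplicate sequence id in ", path, ": ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  }
  pick <- function(p, i) if (length(p) >= i) p[[i]] else NA_character_
  label <- vapply(parts, pick, "", 2)
  species <- vapply(parts, pick, "", 3)
  extra <- vapply(parts, function(p) {
    if (length(p) > 3) paste(p[-(1:3)], collapse = "|") else NA_character_
  }, "")
  if (anyNA(label)) {
    warning(sum(is.na(label)), " header(s) lack the ID|TE_type|Species_ID ",
            "structure; label left absent")
  }
  tibble::tibble(id = id, label = label, species = species, extra = extra,
                 seq = unname(toupper(as.character(set))))
}

#' Write records to FASTA
#'
#' Headers are re-assembled as `ID|TE_type|Species_ID` (fields joined by `|`
#' while present); sequences are wrapped at 80 columns.
#'
#' @param records Tibble with `id`, `seq` and optionally `label`, `species`,
#'   `extra`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(c("id", "seq") %in% names(records)))
  hdr <- records$id
  add <- function(hdr, col) {
    if (col %in% names(records) && !all(is.na(records[[col]]))) {
      v <- records[[col]]
      ifelse(is.na(v), hdr, paste(hdr, v, sep = "|"))
    } else hdr
  }
  hdr <- add(add(add(hdr, "label"), "species"), "extra")
  set <- Biostrings::DNAStringSet(records$seq)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, path, width = 80)
  invisible(path)
}

ambiguity_fraction <- function(seq) {
  n <- nchar(seq)
  canon <- nchar(gsub("[^ACGT]", "", seq))
  (n - canon) / n
}

#' Standard repeat-library preprocessing
#'
#' Applies the three filters in order: (i) drop sequences shorter than
#' `min_len` bp (strictly: 79 bp is dropped, 80 kept); (ii) drop sequences
#' whose non-canonical-base fraction strictly exceeds `max_ambig` (exactly
#' 20% is kept); (iii) drop exact duplicate sequences, keeping the first
#' occurrence (see [dedupe()] for the similarity mode).
#'
#' @param records Records tibble (see [read_fasta()]).
#' @param min_len Minimum length in bp (default 80).
#' @param max_ambig Maximum tolerated ambiguous-base fraction (default 0.20).
#' @return List with `kept` (surviving records, input order) and `rejected`
#'   (tibble `id`, `reason` in `min_len` / `ambiguity` / `duplicate`);
#'   `nrow(kept) + nrow(rejected) == nrow(records)`.
#' @export
preprocess <- function(records, min_len = 80, max_ambig = 0.20) {
  stopifnot(all(c("id", "seq") %in% names(records)))
  records <- tibble::as_tibble(records)
  reasons <- rep(NA_character_, nrow(records))
  short <- nchar(records$seq) < min_len
  reasons[short] <- "min_len"
  ambig <- is.na(reasons) &
    vapply(records$seq, ambiguity_fraction, 0, USE.NAMES = FALSE) > max_ambig
  reasons[ambig] <- "ambiguity"
  alive <- is.na(reasons)
  dupd <- alive & duplicated(replace(records$seq, !alive, NA))
  reasons[dupd] <- "duplicate"
  list(kept = records[is.na(reasons), ],
       rejected = tibble::tibble(id = records$id[!is.na(reasons)],
                                 reason = reasons[!is.na(reasons)]))
}

#' Remove duplicate (or near-duplicate) sequences
#'
#' Default `"exact"` mode removes byte-identical sequences, keeping the first
#' occurrence in input order. `"similarity"` mode greedily clusters records
#' whose k-mer profiles have Jaccard similarity at or above
#' `identity_threshold` (longest-first, each cluster keeps its longest
#' representative); it is deterministic.
#'
#' @param records Records tibble.
#' @param method `"exact"` (default) or `"similarity"`.
#' @param identity_threshold Similarity threshold in `(0, 1]`
#'   (similarity mode only; default 0.9).
#' @param k Word size for the similarity profile (default 8).
#' @return The deduplicated records tibble.
#' @export
dedupe <- function(records, method = c("exact", "similarity"),
                   identity_threshold = 0.9, k = 8) {
  method <- match.arg(method)
  if (method == "exact") return(records[!duplicated(records$seq), ])
  if (identity_threshold <= 0 || identity_threshold > 1) {
    stop("identity_threshold must be in (0, 1]", call. = FALSE)
  }
  ord <- order(-nchar(records$seq), seq_len(nrow(records)))
  sets <- lapply(records$seq[ord], function(s) {
    which(kmer_vector(s, k = k, normalize = FALSE) > 0)
  })
  keep_ord <- logical(length(ord))
  reps <- list()
  for (i in seq_along(ord)) {
    sim <- vapply(reps, function(r) {
      length(intersect(sets[[i]], r)) / length(union(sets[[i]], r))
    }, 0)
    if (length(reps) == 0 || all(sim < identity_threshold)) {
      keep_ord[i] <- TRUE
      reps[[length(reps) + 1]] <- sets[[i]]
    }
  }
  records[sort(ord[keep_ord]), ]
}

#' Stratified train/test split at the leaf level
#'
#' Splits records per leaf label so every TE group is proportionally
#' represented in both subsets: the test set receives `round(n * test_frac)`
#' records per leaf (at least 1 when the leaf has `n >= 2` records; a
#' singleton leaf goes entirely to training).
#'
#' @param records Records tibble; every record must carry a label.
#' @param test_frac Test fraction (default 0.10).
#' @param seed Integer seed for the per-leaf shuffle.
#' @return List with `train` and `test` tibbles (union = input, disjoint).
#' @export
stratified_split <- function(records, test_frac = 0.10, seed = 1) {
  stopifnot("label" %in% names(records))
  if (anyNA(records$label)) {
    stop("unlabeled record(s): ",
         paste(utils::head(records$id[is.na(records$label)], 5), collapse = ", "),
         call. = FALSE)
  }
  old <- .Random.seed_safe()
  set.seed(seed)
  on.exit(.Random.seed_restore(old), add = TRUE)
  test_idx <- unlist(lapply(split(seq_len(nrow(records)), records$label),
                            function(ix) {
    n <- length(ix)
    nt <- if (n >= 2) max(1, round(n * test_frac)) else 0
    if (nt == 0) integer() else sample(ix, nt)
  }), use.names = FALSE)
  list(train = records[setdiff(seq_len(nrow(records)), test_idx), ],
       test = records[sort(test_idx), ])
}

#' Aggregate leaf-labelled records upward into parent-node datasets
#'
#' Each record joins the dataset of every multi-child ancestor ("parent
#' node") on its root-to-label path, tagged with the child of that parent it
#' descends through — the upward aggregation that turns one leaf-labelled
#' library into nine per-node training sets under the default tree.
#'
#' @param records Records tibble with resolvable `label`s.
#' @param tax A `te_taxonomy`.
#' @return Tibble: one row per (record, ancestor parent node), with `parent`,
#'   `class` (the child it descends through) and all record columns. Nest or
#'   split by `parent` to obtain the per-node datasets.
#' @export
build_node_datasets <- function(records, tax) {
  stopifnot(inherits(tax, "te_taxonomy"), "label" %in% names(records))
  pnodes <- parent_nodes(tax)
  purrr::map_dfr(seq_len(nrow(records)), function(i) {
    path <- ancestors(tax, records$label[i])  # errors on unresolvable label
    if (length(path) < 2) return(tibble::tibble())
    par <- path[-length(path)]
    chd <- path[-1]
    keep <- par %in% pnodes
    if (!any(keep)) return(tibble::tibble())
    dplyr::bind_cols(tibble::tibble(parent = par[keep], class = chd[keep]),
                     records[rep(i, sum(keep)), ])
  })
}
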