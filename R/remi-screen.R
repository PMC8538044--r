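# Pooled insertional-mutagenesis selection screens: count normalization,
# abundance binning, log fold changes and binned Z-scores, mutant selection,
# gene assignment, overlap / rank-quartile / GO over-representation tests.

#' Normalize raw insertion read counts to reads per million
#'
#' Reads mapping to different sequence tags of the same insertion point are
#' summed, non-uniquely mapped records are dropped, and every sample
#' (screen x replicate x round) is scaled to reads per million, making the
#' matrix invariant to sequencing depth.
#'
#' @param counts Long data frame with columns `insertion_id`, `screen`,
#'   `replicate`, `round`, `count`, optionally `tag` (multiple tags per
#'   insertion are summed) and `unique_mapping` (records with `FALSE` are
#'   removed before scaling).
#'
#' @return An object of class `screen_counts`: a list with `counts` (matrix,
#'   mutants x samples, RPM) and `samples` (data frame `sample_id, screen,
#'   replicate, round`).
#' @details Duplicate `(insertion, sample)` rows are rejected unless a `tag`
#'   column distinguishes them.
#' @examples
#' sim <- gen_screen_counts(screen_sim_config(seed = 1, n_mutants = 20,
#'                                            read_depth = 1e4))
#' sc <- normalize_counts(sim$counts)
#' dim(sc$counts)
#' @export
normalize_counts <- function(counts) {
  req <- c("insertion_id", "screen", "replicate", "round", "count")
  stopifnot(is.data.frame(counts), all(req %in% names(counts)))
  if ("unique_mapping" %in% names(counts))
    counts <- counts[counts$unique_mapping, , drop = FALSE]
  sample_id <- paste(counts$screen, counts$replicate, counts$round, sep = "|")
  if ("tag" %in% names(counts)) {
    if (anyDuplicated(paste(counts$insertion_id, counts$tag, sample_id)))
      stop("duplicate (insertion, tag, sample) rows", call. = FALSE)
  } else if (anyDuplicated(paste(counts$insertion_id, sample_id))) {
    stop("duplicate (insertion, sample) rows", call. = FALSE)
  }
  muts <- sort(unique(counts$insertion_id))
  sids <- unique(sample_id)
  m <- matrix(0, nrow = length(muts), ncol = length(sids),
              dimnames = list(muts, sids))
  agg <- tapply(counts$count,
                list(factor(counts$insertion_id, muts),
                     factor(sample_id, sids)), sum)
  agg[is.na(agg)] <- 0
  m[, ] <- agg
  tot <- colSums(m)
  if (any(tot <= 0)) stop("sample totals must be > 0", call. = FALSE)
  m <- sweep(m, 2, tot / 1e6, "/")
  meta <- do.call(rbind, strsplit(sids, "|", fixed = TRUE))
  structure(list(counts = m,
                 samples = data.frame(sample_id = sids, screen = meta[, 1],
                                      replicate = as.integer(meta[, 2]),
                                      round = as.integer(meta[, 3]),
                                      stringsAsFactors = FALSE)),
            class = "screen_counts")
}

.sample_cols <- function(sc, screen = NULL, round = NULL, replicate = NULL) {
  keep <- rep(TRUE, nrow(sc$samples))
  if (!is.null(screen)) keep <- keep & sc$samples$screen == screen
  if (!is.null(round)) keep <- keep & sc$samples$round == round
  if (!is.null(replicate)) keep <- keep & sc$samples$replicate == replicate
  sc$samples$sample_id[keep]
}

#' Bin mutants by their mean control (vehicle) read count
#'
#' Mutants are binned by the mean of their normalized read counts across the
#' control-screen replicates at the given round: `bin100` below 100 reads,
#' `bin1000` for 100-1000 reads inclusive, `bin10000` above 1000 reads.  The
#' bins group mutants of similar abundance so that Z-scores are computed
#' among comparably-sampled mutants; `bin100` mutants are excluded from the
#' disadvantage analysis because their technical dropout rate is high.
#'
#' @param sc A [normalize_counts()] object.
#' @param round Screen round whose control counts are binned.
#' @param control_screen Name of the vehicle screen (default `"vehicle"`).
#' @return Factor of bins (`bin100`, `bin1000`, `bin10000`) named by mutant.
#' @export
bin_mutants <- function(sc, round, control_screen = "vehicle") {
  stopifnot(inherits(sc, "screen_counts"))
  cols <- .sample_cols(sc, screen = control_screen, round = round)
  if (length(cols) < 1) stop("no control samples for round ", round,
                             call. = FALSE)
  mu <- rowMeans(sc$counts[, cols, drop = FALSE])
  bins <- ifelse(mu < 100, "bin100", ifelse(mu <= 1000, "bin1000", "bin10000"))
  factor(stats::setNames(bins, rownames(sc$counts)),
         levels = c("bin100", "bin1000", "bin10000"))
}

#' Per-mutant log fold changes and binned Z-scores
#'
#' For every replicate of the chosen screen and round, the log2 fold change
#' of each mutant's normalized count relative to the mean of the control
#' replicates is computed with a pseudocount, and standardized to a Z-score
#' within its abundance bin: `z = (lfc - mean_bin(lfc)) / sd_bin(lfc)`,
#' separately per (bin, replicate).
#'
#' @param sc A [normalize_counts()] object.
#' @param screen Screen to score (e.g. `"drug"`).
#' @param round Round to score (2 or 5 in the reference design).
#' @param control_screen Vehicle screen name.
#' @param pseudocount Added to numerator and denominator before the log
#'   (default 1).
#' @return Data frame of class `selection_calls`, long over replicates:
#'   `insertion_id, screen, round, replicate, bin, lfc, z`.  Bins with fewer
#'   than 3 members get `z = NA` with a warning (such mutants stay neutral).
#' @export
compute_lfc_z <- function(sc, screen, round, control_screen = "vehicle",
                          pseudocount = 1) {
  stopifnot(inherits(sc, "screen_counts"))
  ctrl_cols <- .sample_cols(sc, screen = control_screen, round = round)
  if (length(ctrl_cols) < 1) stop("control samples missing", call. = FALSE)
  dmso_mean <- rowMeans(sc$counts[, ctrl_cols, drop = FALSE])
  bins <- bin_mutants(sc, round, control_screen)
  reps <- sort(unique(sc$samples$replicate[sc$samples$screen == screen &
                                             sc$samples$round == round]))
  if (length(reps) < 1) stop("no samples for screen ", screen, " round ",
                             round, call. = FALSE)
  small_bins <- names(which(table(bins) > 0 & table(bins) < 3))
  if (length(small_bins))
    warning("bin(s) with < 3 members, Z undefined: ",
            paste(small_bins, collapse = ", "), call. = FALSE)
  out <- lapply(reps, function(r) {
    col <- .sample_cols(sc, screen = screen, round = round, replicate = r)
    lfc <- log2((sc$counts[, col] + pseudocount) / (dmso_mean + pseudocount))
    z <- rep(NA_real_, length(lfc))
    for (b in levels(bins)) {
      i <- which(bins == b)
      if (length(i) >= 3) z[i] <- (lfc[i] - mean(lfc[i])) / stats::sd(lfc[i])
    }
    data.frame(insertion_id = rownames(sc$counts), screen = screen,
               round = round, replicate = r, bin = as.character(bins),
               lfc = unname(lfc), z = z, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  class(out) <- c("selection_calls", "data.frame")
  out
}

#' Select advantaged and disadvantaged mutants from two screen rounds
#'
#' Advantaged mutants have `z > z_adv` in *both* biological replicates at the
#' late round (resistance accumulates with selection); disadvantaged mutants
#' have `z < z_dis` in both replicates at the early round (hypersensitive
#' mutants drop out quickly) and must not sit in `bin100`, whose dropout is
#' technical.  A mutant qualifying for both sets is conflicting and excluded
#' from both with a warning, keeping the sets disjoint.
#'
#' @param calls_early `selection_calls` for the early round (round 2).
#' @param calls_late `selection_calls` for the late round (round 5).
#' @param z_adv Advantage threshold (default 1.5).
#' @param z_dis Disadvantage threshold (default -1).
#' @return List with character vectors `advantaged`, `disadvantaged` and
#'   `conflicting`.
#' @export
select_mutants <- function(calls_early, calls_late, z_adv = 1.5, z_dis = -1) {
  all_reps <- function(calls, pred) {
    ok <- tapply(pred(calls$z), calls$insertion_id,
                 function(v) all(!is.na(v)) && all(v))
    names(which(ok))
  }
  adv <- all_reps(calls_late, function(z) z > z_adv)
  dis <- all_reps(calls_early, function(z) z < z_dis)
  bin_early <- tapply(calls_early$bin, calls_early$insertion_id,
                      function(b) b[1])
  dis <- dis[bin_early[dis] != "bin100"]
  conflict <- intersect(adv, dis)
  if (length(conflict)) {
    warning(length(conflict),
            " mutant(s) met both advantage and disadvantage criteria; ",
            "excluded from both sets", call. = FALSE)
    adv <- setdiff(adv, conflict)
    dis <- setdiff(dis, conflict)
  }
  list(advantaged = adv, disadvantaged = dis, conflicting = conflict)
}

#' Annotate insertion points against gene models
#'
#' Classifies every insertion as `intragenic` (within a gene body),
#' `promoter_within_500bp` (intergenic but at most 500 bp upstream of a
#' gene's transcription start, strand-aware) or `intergenic`.  Intragenic and
#' promoter insertions are assigned to the host/downstream gene; an insertion
#' upstream of two divergent genes goes to the nearer start (ties to the
#' first gene in id order, noted in `note`).  Insertions whose assigned gene
#' is a tRNA, pseudogene or transposable element carry the corresponding
#' `excluded_class`.
#'
#' @param insertions Data frame `insertion_id, chrom, pos` (1-based).
#' @param genes Gene-model data frame `gene_id, chrom, start, end, strand,
#'   type` (1-based inclusive; see [read_gene_models()]).
#' @param promoter_bp Upstream window in bp (default 500; the assignment rule
#'   is "< `promoter_bp` + 1", i.e. distance <= 500).
#' @return Data frame `insertion_id, chrom, pos, category, assigned_gene,
#'   excluded_class, note`.
#' @export
annotate_insertions <- function(insertions, genes, promoter_bp = 500L) {
  stopifnot(all(c("insertion_id", "chrom", "pos") %in% names(insertions)),
            all(c("gene_id", "chrom", "start", "end", "strand", "type")
                %in% names(genes)))
  excl_types <- c(tRNA = "tRNA", pseudogene = "pseudogene",
                  transposable_element = "transposable_element")
  rows <- lapply(seq_len(nrow(insertions)), function(i) {
    ins <- insertions[i, ]
    g <- genes[genes$chrom == ins$chrom, , drop = FALSE]
    category <- "intergenic"; gene <- NA_character_; note <- NA_character_
    hit <- g[g$start <= ins$pos & ins$pos <= g$end, , drop = FALSE]
    if (nrow(hit) > 0) {
      category <- "intragenic"
      if (nrow(hit) > 1) note <- "overlapping genes; first taken"
      gene <- hit$gene_id[1]
    } else {
      # strand-aware upstream distance to each gene's transcription start
      dist <- ifelse(g$strand == "+", g$start - ins$pos, ins$pos - g$end)
      cand <- which(dist >= 1 & dist <= promoter_bp)
      if (length(cand) > 0) {
        category <- "promoter_within_500bp"
        o <- cand[order(dist[cand], g$gene_id[cand])]
        if (length(cand) > 1)
          note <- "within promoter window of multiple genes; nearest start taken"
        gene <- g$gene_id[o[1]]
      }
    }
    excl <- "none"
    if (!is.na(gene)) {
      ty <- genes$type[match(gene, genes$gene_id)]
      if (ty %in% names(excl_types)) excl <- excl_types[[ty]]
    }
    data.frame(insertion_id = ins$insertion_id, chrom = ins$chrom,
               pos = ins$pos, category = category, assigned_gene = gene,
               excluded_class = excl, note = note, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assign selected mutants to genes and apply the exclusion filters
#'
#' Maps selected insertion mutants to genes via their annotations and removes
#' (a) insertions in tRNAs, pseudogenes or transposable elements, (b) genes
#' on the blacklist (e.g. generic axenic-growth mutants), and (c) intergenic
#' insertions outside the 500 bp promoter window, which get no gene.  All
#' mutants are retained in the returned table with their inclusion status;
#' `genes` holds the resulting unique gene list.
#'
#' @param mutant_ids Character vector of selected insertion mutants.
#' @param annotations Output of [annotate_insertions()] covering every id.
#' @param blacklist Character vector of gene ids to remove.
#' @return List with `genes` (character) and `table` (per-mutant data frame
#'   with `included` and `reason`).
#' @export
assign_genes <- function(mutant_ids, annotations, blacklist = character()) {
  miss <- setdiff(mutant_ids, annotations$insertion_id)
  if (length(miss))
    stop("unknown mutant id(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  ann <- annotations[match(mutant_ids, annotations$insertion_id), ,
                     drop = FALSE]
  reason <- rep("assigned", nrow(ann))
  included <- rep(TRUE, nrow(ann))
  drop_excl <- ann$excluded_class != "none"
  included[drop_excl] <- FALSE
  reason[drop_excl] <- paste0("excluded_class:", ann$excluded_class[drop_excl])
  no_gene <- !drop_excl & is.na(ann$assigned_gene)
  included[no_gene] <- FALSE
  reason[no_gene] <- "intergenic_no_promoter"
  bl <- included & ann$assigned_gene %in% blacklist
  included[bl] <- FALSE
  reason[bl] <- "blacklisted_gene"
  list(genes = unique(ann$assigned_gene[included]),
       table = data.frame(insertion_id = mutant_ids,
                          assigned_gene = ann$assigned_gene,
                          category = ann$category,
                          excluded_class = ann$excluded_class,
                          included = included, reason = reason,
                          stringsAsFactors = FALSE))
}

#' Hypergeometric overlap test between two gene lists
#'
#' Upper-tail hypergeometric probability of observing at least the realized
#' overlap when drawing `|A|` genes from the universe with `|B|` marked:
#' `P(X >= |A intersect B|)`.
#'
#' @param list_a,list_b Character vectors, both subsets of `universe`.
#' @param universe Character vector of all eligible genes.
#' @return List of class `enrichment_result` with `k` (overlap), `K`
#'   (`|A|`), `n` (`|B|`), `N` (universe size) and `p`.
#' @examples
#' overlap_test(letters[1:5], letters[1:5], letters[1:20])
#' @export
overlap_test <- function(list_a, list_b, universe) {
  list_a <- unique(list_a); list_b <- unique(list_b)
  universe <- unique(universe)
  if (!all(list_a %in% universe) || !all(list_b %in% universe))
    stop("gene lists must be subsets of the universe", call. = FALSE)
  k <- length(intersect(list_a, list_b))
  K <- length(list_a); n <- length(list_b); N <- length(universe)
  p <- stats::phyper(k - 1, n, N - n, K, lower.tail = FALSE)
  structure(list(label = "overlap", k = k, K = K, n = n, N = N, p = p),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> %s: k=%d of K=%d drawn, n=%d marked, N=%d (p=%s)\n",
              x$label, x$k, x$K, x$n, x$N, format(signif(x$p, 4))))
  invisible(x)
}

#' Rank-quartile enrichment of one screen's hits in another screen's ranking
#'
#' All mutants scored in screen X are ranked by their mean Z-score across
#' replicates (ascending: Q1 holds the most decreased mutants, Q4 the most
#' increased; ties broken by stable mutant-id order) and split into quartiles
#' whose sizes differ by at most one.  The quartile counts of the listed
#' (screen-Y) mutants are compared with a uniform expectation by a
#' chi-squared goodness-of-fit test on 3 degrees of freedom.
#'
#' @param z_mean Named numeric vector: mean Z per mutant in screen X.
#' @param listed Character vector of mutants (hits from screen Y); all must
#'   be scored in `z_mean`.
#' @return List with `counts` (Q1-Q4), `expected`, `chi_squared`, `df`, `p`.
#' @export
rank_quartile_test <- function(z_mean, listed) {
  if (is.null(names(z_mean))) stop("z_mean must be named", call. = FALSE)
  miss <- setdiff(listed, names(z_mean))
  if (length(miss))
    stop("listed mutant(s) not scored: ", paste(miss, collapse = ", "),
         call. = FALSE)
  o <- order(z_mean, names(z_mean))
  N <- length(z_mean)
  quart <- integer(N)
  quart[o] <- ceiling(4 * seq_len(N) / N)
  names(quart) <- names(z_mean)
  counts <- tabulate(quart[listed], nbins = 4)
  names(counts) <- paste0("Q", 1:4)
  n <- length(listed)
  chi <- sum((counts - n / 4)^2 / (n / 4))
  p <- stats::pchisq(chi, df = 3, lower.tail = FALSE)
  list(counts = counts, expected = rep(n / 4, 4), chi_squared = chi, df = 3,
       p = p)
}

#' GO term over-representation by hypergeometric test
#'
#' For every term, tests whether the gene list is enriched for the term's
#' annotated genes relative to the universe (upper-tail hypergeometric).  The
#' universe must already carry the same exclusions as the gene lists (no
#' tRNAs, pseudogenes, transposable elements or non-promoter intergenics).
#' No multiplicity correction is applied by default; Benjamini-Hochberg is
#' available via `adjust = "BH"`.
#'
#' @param gene_list Character vector, subset of `universe`.
#' @param universe Character vector of eligible genes.
#' @param term2gene Data frame with columns `term`, `gene`.
#' @param alpha Significance cutoff on the (adjusted) p-value (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Data frame `term, k, K, n, N, p, p_adjusted` of significant terms,
#'   sorted by ascending p.  Terms annotating no universe gene are skipped.
#' @export
go_enrichment <- function(gene_list, universe, term2gene, alpha = 0.05,
                          adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(all(c("term", "gene") %in% names(term2gene)))
  universe <- unique(universe)
  gene_list <- unique(gene_list)
  if (!all(gene_list %in% universe))
    stop("gene list must be a subset of the universe", call. = FALSE)
  t2g <- term2gene[term2gene$gene %in% universe, , drop = FALSE]
  terms <- unique(t2g$term)
  K <- length(gene_list); N <- length(universe)
  rows <- lapply(terms, function(tm) {
    tg <- unique(t2g$gene[t2g$term == tm])
    n <- length(tg)
    if (n == 0) return(NULL)
    k <- length(intersect(tg, gene_list))
    p <- stats::phyper(k - 1, n, N - n, K, lower.tail = FALSE)
    data.frame(term = tm, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0)
    return(data.frame(term = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      p_adjusted = numeric()))
  out$p_adjusted <- if (adjust == "BH") stats::p.adjust(out$p, "BH") else out$p
  out <- out[out$p_adjusted < alpha, , drop = FALSE]
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}
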