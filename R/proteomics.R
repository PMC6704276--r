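#' Protein LFQ intensity table
#'
#' Label-free quantification intensities of proteins across the
#' microdissected MSI segments, with MaxQuant-style QC flags per protein.
#'
#' @param protein_id character vector of unique protein identifiers.
#' @param intensities n_proteins x n_segments matrix of LFQ intensities,
#'   finite and >= 0 (0 = not quantified).
#' @param flags list (one element per protein) of character vectors drawn
#'   from `"reverse"`, `"only_identified_by_site"`,
#'   `"potential_contaminant"`; or `NULL` for no flags.
#' @param segment_names column labels; default `colnames(intensities)` or
#'   `segment_1..n`.
#' @return an object of class `"protein_table"`.
#' @export
protein_table <- function(protein_id, intensities, flags = NULL,
                          segment_names = NULL) {
  intensities <- as.matrix(intensities)
  protein_id <- as.character(protein_id)
  if (anyDuplicated(protein_id)) stop("protein ids must be unique")
  if (length(protein_id) != nrow(intensities))
    stop("protein_id length and intensity rows differ")
  if (ncol(intensities) < 2) stop("at least 2 segment columns are required")
  if (any(!is.finite(intensities)) || any(intensities < 0))
    stop("intensities must be finite and non-negative")
  if (is.null(segment_names))
    segment_names <- colnames(intensities)
  if (is.null(segment_names))
    segment_names <- paste0("segment_", seq_len(ncol(intensities)))
  if (is.null(flags)) flags <- rep(list(character(0)), length(protein_id))
  valid <- c("reverse", "only_identified_by_site", "potential_contaminant")
  bad <- setdiff(unlist(flags), valid)
  if (length(bad)) stop("unknown flag(s): ", paste(bad, collapse = ", "))
  dimnames(intensities) <- list(protein_id, segment_names)
  structure(list(protein_id = protein_id, intensities = intensities,
                 flags = flags, segment_names = segment_names),
            class = "protein_table")
}

#' @export
print.protein_table <- function(x, ...) {
  cat(sprintf("<protein_table> %d proteins x %d segments (%d flagged)\n",
              length(x$protein_id), length(x$segment_names),
              sum(lengths(x$flags) > 0)))
  invisible(x)
}

#' Read a MaxQuant-style proteinGroups table
#'
#' Expects a TSV with columns `Protein IDs`, the flag columns `Reverse`,
#' `Only identified by site`, `Potential contaminant` (marked with `+`),
#' and one `LFQ intensity <segment>` column per segment.
#'
#' @param path file path.
#' @return a [protein_table()].
#' @export
read_protein_groups <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  if (!"Protein IDs" %in% names(tab)) stop("missing 'Protein IDs' column")
  lfq_cols <- grep("^LFQ intensity ", names(tab), value = TRUE)
  if (length(lfq_cols) < 2) stop("need >= 2 'LFQ intensity <segment>' columns")
  flag_map <- c(Reverse = "reverse",
                `Only identified by site` = "only_identified_by_site",
                `Potential contaminant` = "potential_contaminant")
  flags <- lapply(seq_len(nrow(tab)), function(i) {
    present <- names(flag_map)[vapply(names(flag_map), function(cn)
      cn %in% names(tab) && grepl("\\+", as.character(tab[[cn]][i])), TRUE)]
    unname(flag_map[present])
  })
  intens <- as.matrix(tab[, lfq_cols])
  colnames(intens) <- sub("^LFQ intensity ", "", lfq_cols)
  protein_table(tab[["Protein IDs"]], intens, flags)
}

#' Remove flagged proteins
#'
#' Drops every protein flagged as reverse-database hit, only identified by
#' site, or potential contaminant. A protein carrying several flags is
#' removed once but counted under each flag in the report.
#'
#' @param t a [protein_table()].
#' @return the filtered `protein_table`; attribute `"removed"` is a named
#'   count per flag.
#' @export
filter_flagged <- function(t) {
  stopifnot(inherits(t, "protein_table"))
  all_flags <- c("reverse", "only_identified_by_site", "potential_contaminant")
  counts <- vapply(all_flags, function(f)
    sum(vapply(t$flags, function(x) f %in% x, TRUE)), integer(1))
  keep <- lengths(t$flags) == 0
  out <- protein_table(t$protein_id[keep],
                       t$intensities[keep, , drop = FALSE],
                       t$flags[keep], t$segment_names)
  attr(out, "removed") <- counts
  out
}

#' Log2-transform and z-score LFQ intensities per protein
#'
#' Intensities are log2-transformed (zeros treated as missing, not
#' `log2(0)`), then standardized per protein row: `z = (x - mean) / sd`
#' with the sample SD (n - 1 denominator; set `population_sd = TRUE` for
#' the n denominator). Rows with fewer than `min_valid` quantified
#' segments are excluded; rows that are constant across segments get
#' `z = 0` everywhere and are flagged.
#'
#' @param t a [protein_table()].
#' @param min_valid minimum quantified (non-zero) segments per protein.
#' @param population_sd use the population SD instead of the sample SD.
#' @return z-score matrix (retained proteins x segments), possibly with
#'   `NA` where an intensity was missing; attributes `"excluded"` (ids of
#'   dropped rows) and `"constant"` (ids of constant rows).
#' @examples
#' t <- protein_table("p1", matrix(c(4, 2, 2), 1), NULL,
#'                    paste0("segment_", 1:3))
#' log2_zscore(t)  # 1.1547, -0.5774, -0.5774
#' @export
log2_zscore <- function(t, min_valid = ncol(t$intensities),
                        population_sd = FALSE) {
  stopifnot(inherits(t, "protein_table"))
  x <- t$intensities
  x[x == 0] <- NA
  lx <- log2(x)
  valid <- rowSums(is.finite(lx))
  keep <- valid >= max(2L, min_valid)
  lx <- lx[keep, , drop = FALSE]
  mu <- rowMeans(lx, na.rm = TRUE)
  sd <- apply(lx, 1, stats::sd, na.rm = TRUE)
  if (population_sd) {
    n <- rowSums(is.finite(lx))
    sd <- sd * sqrt((n - 1) / n)
  }
  const <- is.na(sd) | sd < 1e-12
  z <- (lx - mu) / ifelse(const, 1, sd)
  z[const, ] <- ifelse(is.finite(lx[const, , drop = FALSE]), 0, NA)
  structure(z,
            excluded = t$protein_id[!keep],
            constant = rownames(lx)[const])
}

#' Exclusive over/under-expression calls from z-scores
#'
#' A protein is called over-expressed in segment `s` when its z-score is
#' `>= threshold` in `s` and below the threshold in every other segment
#' (so the call is exclusive to one segment); under-expression is the
#' mirror image at `<= -threshold`. Proteins crossing the bound in two or
#' more segments yield no call.
#'
#' @param z z-score matrix from [log2_zscore()] (rows named by protein).
#' @param threshold exclusivity threshold on the z-score (default 1).
#' @return data frame with columns `protein_id`, `segment`, `direction`
#'   (`"over"` or `"under"`), zero rows when nothing is exclusive.
#' @export
classify_exclusive <- function(z, threshold = 1.0) {
  z <- as.matrix(z)
  segs <- colnames(z)
  if (is.null(segs)) segs <- paste0("segment_", seq_len(ncol(z)))
  ids <- rownames(z)
  if (is.null(ids)) ids <- paste0("protein_", seq_len(nrow(z)))
  calls <- list()
  for (dir in c("over", "under")) {
    hit <- if (dir == "over") z >= threshold else z <= -threshold
    hit[is.na(hit)] <- FALSE
    nhit <- rowSums(hit)
    idx <- which(nhit == 1)
    if (length(idx))
      calls[[dir]] <- data.frame(
        protein_id = ids[idx],
        segment = segs[apply(hit[idx, , drop = FALSE], 1, which)],
        direction = dir, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, calls)
  if (is.null(out))
    out <- data.frame(protein_id = character(0), segment = character(0),
                      direction = character(0))
  rownames(out) <- NULL
  out
}

#' Hierarchical clustering of proteins with k-means preprocessing
#'
#' Perseus-style protein clustering: the rows are first partitioned by
#' k-means (Euclidean) into at most `n_pre_clusters` groups with a capped
#' iteration count and a given number of restarts, then the group
#' centroids are clustered agglomeratively with complete linkage and
#' Euclidean distance. Every protein inherits the leaf position of its
#' centroid. Defaults follow the conventional 300 clusters / 10 iterations
#' / 1 restart preprocessing.
#'
#' @param z numeric matrix (proteins x segments); rows with `NA` are
#'   dropped.
#' @param n_pre_clusters k for the k-means preprocessing (capped at the
#'   number of distinct rows).
#' @param kmeans_iterations,kmeans_restarts k-means iteration cap and
#'   number of random starts.
#' @param seed integer seed for the k-means initialization.
#' @return a list of class `"protein_clustering"`: `hclust` (the centroid
#'   dendrogram, class `stats::hclust`), `centroid_of` (centroid index per
#'   protein), `row_order` (protein ids in dendrogram leaf order),
#'   `heights` (merge heights, non-decreasing).
#' @export
hierarchical_cluster <- function(z, n_pre_clusters = 300L,
                                 kmeans_iterations = 10L,
                                 kmeans_restarts = 1L, seed = 1L) {
  z <- as.matrix(z)
  ids <- rownames(z)
  if (is.null(ids)) ids <- paste0("protein_", seq_len(nrow(z)))
  ok <- stats::complete.cases(z)
  z <- z[ok, , drop = FALSE]; ids <- ids[ok]
  if (nrow(z) < 2) stop("need at least 2 complete protein rows")
  uz <- unique(z)
  k <- min(n_pre_clusters, nrow(uz))
  if (k >= nrow(uz)) {
    # every distinct row is its own centroid; k-means would be a no-op
    key <- apply(z, 1, paste, collapse = "\r")
    km <- list(cluster = match(key, unique(key)), centers = uz)
  } else {
    km <- with_seed(seed,
      suppressWarnings(stats::kmeans(z, centers = k,
                                     iter.max = kmeans_iterations,
                                     nstart = kmeans_restarts)))
  }
  hc <- stats::hclust(stats::dist(km$centers), method = "complete")
  leaf_pos <- order(hc$order)            # centroid -> position in dendrogram
  row_order <- ids[order(leaf_pos[km$cluster])]
  structure(list(hclust = hc, centroid_of = km$cluster,
                 row_order = row_order, heights = hc$height),
            class = "protein_clustering")
}

#' Write a protein dendrogram in Newick format
#'
#' Serializes the centroid dendrogram of [hierarchical_cluster()] as a
#' Newick tree (via \pkg{ape}), with centroid leaves named `c<i>`.
#'
#' @param pc a `"protein_clustering"` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(pc, path) {
  stopifnot(inherits(pc, "protein_clustering"))
  hc <- pc$hclust
  hc$labels <- paste0("c", seq_len(nrow(as.matrix(stats::cophenetic(hc)))))
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Write regulation calls as TSV
#' @param calls data frame from [classify_exclusive()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
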