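#' All-vs-all divergence matrix of monomers
#'
#' Computes the symmetric matrix of pairwise divergences ([divergence()]:
#' edit distance over the longer length) between all monomer sequences.
#' This matrix carries the "< 5% divergence" relation that defines monomer
#' families.
#'
#' @param x an `hor_monomers` data frame or a character vector of sequences.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
build_divergence_matrix <- function(x) {
  seqs <- monomer_sequences(x)
  if (length(seqs) < 1) stop_input("need at least one monomer")
  raw <- .edit_distance_matrix_cpp(seqs)
  len <- nchar(seqs)
  denom <- outer(len, len, pmax)
  d <- raw / denom
  diag(d) <- 0
  dimnames(d) <- NULL
  d
}

monomer_sequences <- function(x) {
  if (is.data.frame(x)) {
    if (is.null(x$sequence)) stop_input("monomer data frame lacks a 'sequence' column")
    seqs <- x$sequence
  } else if (is.character(x)) {
    seqs <- x
  } else {
    stop_input("expected an hor_monomers data frame or a character vector")
  }
  if (length(seqs) && any(!nzchar(seqs))) stop_input("empty monomer sequence")
  toupper(seqs)
}

#' Assign monomers to families at a divergence threshold
#'
#' Families (monomer types) are the connected components of the graph whose
#' edges join monomer pairs with divergence strictly below `threshold`
#' (single-linkage transitive closure, the order-independent reading of
#' "all monomers that differ from each other by less than 5%"). Labels are
#' dense integers renumbered by first occurrence along the enumeration, so
#' the first monomer always belongs to family 1 (rendered `t1`).
#'
#' @param x a divergence matrix from [build_divergence_matrix()], an
#'   `hor_monomers` data frame, or a character vector of sequences.
#' @param threshold divergence threshold in (0, 0.5); default 0.05, the
#'   classical intra-type bound for alpha satellite.
#' @param method how to cluster when `x` holds sequences: `"exact"` builds
#'   the full divergence matrix; `"stream"` compares each monomer to running
#'   family representatives (a scale guard for large N that agrees with the
#'   exact mode whenever families are tight relative to `threshold`);
#'   `"auto"` picks `"exact"` for up to 600 monomers. Ignored when `x` is
#'   already a matrix.
#' @return integer vector of family labels (1-based, first-occurrence order).
#' @export
assign_families <- function(x, threshold = 0.05,
                            method = c("auto", "exact", "stream")) {
  method <- match.arg(method)
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 0.5) {
    stop_param("threshold must lie strictly between 0 and 0.5")
  }
  if (is.matrix(x)) return(families_from_matrix(x, threshold))
  seqs <- monomer_sequences(x)
  if (length(seqs) == 0) return(integer(0))
  if (method == "auto") method <- if (length(seqs) <= 600) "exact" else "stream"
  if (method == "exact") {
    families_from_matrix(build_divergence_matrix(seqs), threshold)
  } else {
    assign_families_stream(seqs, threshold)
  }
}

families_from_matrix <- function(d, threshold) {
  n <- nrow(d)
  if (n == 0) return(integer(0))
  if (!isTRUE(all.equal(d, t(d))) || any(diag(d) != 0)) {
    stop_input("divergence matrix must be symmetric with zero diagonal")
  }
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  edges <- which(d < threshold & upper.tri(d), arr.ind = TRUE)
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      ri <- find(edges[k, 1])
      rj <- find(edges[k, 2])
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  renumber_first_occurrence(roots)
}

renumber_first_occurrence <- function(labels) {
  as.integer(match(labels, unique(labels)))
}

# Streaming representative-first assignment (scale guard). Each monomer is
# compared against one representative per family; families hit below the
# threshold are merged. Representatives start as the family's first member
# and are refreshed to a star consensus of the earliest members as the
# family grows (sizes 8, 16, 32, ...).
assign_families_stream <- function(seqs, threshold) {
  n <- length(seqs)
  labels <- integer(n)
  reps <- character(0)        # representative per family
  members <- list()           # member indices per family
  next_refresh <- integer(0)
  for (i in seq_len(n)) {
    hit <- integer(0)
    if (length(reps)) {
      dv <- .edit_distance_to_ref_cpp(reps, seqs[i]) /
        pmax(nchar(reps), nchar(seqs[i]))
      hit <- which(dv < threshold)
    }
    if (length(hit) == 0) {
      reps <- c(reps, seqs[i])
      members[[length(members) + 1L]] <- i
      next_refresh <- c(next_refresh, 8L)
      labels[i] <- length(members)
    } else {
      f <- hit[1]
      if (length(hit) > 1) {
        for (g in rev(hit[-1])) {
          members[[f]] <- c(members[[f]], members[[g]])
          labels[labels == g] <- f
          labels[labels > g] <- labels[labels > g] - 1L
          members[[g]] <- NULL
          reps <- reps[-g]
          next_refresh <- next_refresh[-g]
          if (f > g) f <- f - 1L
        }
        members[[f]] <- sort(members[[f]])
      }
      members[[f]] <- c(members[[f]], i)
      labels[i] <- f
      if (length(members[[f]]) >= next_refresh[f]) {
        anchor_ids <- utils::head(sort(members[[f]]), 32L)
        reps[f] <- star_consensus(seqs[anchor_ids], seqs[sort(members[[f]])[1]])
        next_refresh[f] <- next_refresh[f] * 2L
      }
    }
  }
  # Single-linkage repair: a monomer can sit beyond the threshold from its
  # family's representative yet within it of some member (the transitive
  # closure the exact mode computes). Members of tiny families are checked
  # against all monomers and absorbed where a sub-threshold link exists.
  for (pass in 1:5) {
    sizes <- tabulate(labels)
    merged <- FALSE
    for (f in which(sizes <= 3L)) {
      for (i in which(labels == f)) {
        dv <- .edit_distance_to_ref_cpp(seqs, seqs[i]) /
          pmax(nchar(seqs), nchar(seqs[i]))
        dv[labels == f] <- Inf
        j <- which.min(dv)
        if (dv[j] < threshold) {
          labels[labels == f] <- labels[j]
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) break
  }
  renumber_first_occurrence(labels)
}

#' Per-family consensus sequences
#'
#' For each family, members are star-aligned against the family medoid (the
#' member minimizing summed divergence to the rest; ties go to the earliest
#' member) and the consensus takes the majority base per medoid column, with
#' ties broken in the order A < C < G < T. Columns where a gap outvotes
#' every base are dropped; insertions relative to the medoid are ignored.
#'
#' @param x `hor_monomers` data frame or character vector of sequences.
#' @param labels integer family labels as returned by [assign_families()].
#' @return named character vector of consensus sequences, names `t1..tk`.
#' @export
family_consensus <- function(x, labels) {
  seqs <- monomer_sequences(x)
  if (length(seqs) != length(labels)) stop_input("labels and sequences differ in length")
  if (length(seqs) == 0) stop_input("no monomers")
  fams <- sort(unique(labels))
  out <- vapply(fams, function(f) {
    mem <- seqs[labels == f]
    if (length(mem) == 1) return(mem)
    raw <- .edit_distance_matrix_cpp(mem)
    denom <- outer(nchar(mem), nchar(mem), pmax)
    med <- which.min(rowSums(raw / denom))
    star_consensus(mem, mem[med])
  }, character(1))
  names(out) <- fmt_family(fams)
  out
}

# Star alignment of members onto an anchor; majority base per anchor column.
star_consensus <- function(members, anchor) {
  M <- star_align_matrix(members, anchor)
  counts <- apply(M, 2, function(col) {
    c(tabulate(match(col, DNA_BASES), nbins = 4L), sum(col == "-"))
  })
  base_idx <- apply(counts[1:4, , drop = FALSE], 2, which.max)
  base_max <- counts[cbind(base_idx, seq_len(ncol(counts)))]
  keep <- counts[5, ] <= base_max & base_max > 0
  paste(DNA_BASES[base_idx[keep]], collapse = "")
}

# Align each member globally to the anchor (unit-cost edit distance,
# deterministic traceback) and project onto anchor columns; returns a
# character matrix members x columns.
star_align_matrix <- function(members, anchor) {
  rows <- vapply(members, function(mb) .project_onto_anchor_cpp(mb, anchor),
                 character(1), USE.NAMES = FALSE)
  do.call(rbind, strsplit(rows, ""))
}

#' Cluster monomers into families and compute consensi
#'
#' Convenience wrapper bundling [assign_families()] and [family_consensus()]
#' and reporting each monomer's divergence to its family consensus.
#'
#' @inheritParams assign_families
#' @return object of class `hor_families`: list with `labels`, `k`,
#'   `consensus` (named `t1..tk`), and `div_to_consensus`.
#' @export
hor_families <- function(x, threshold = 0.05,
                         method = c("auto", "exact", "stream")) {
  seqs <- monomer_sequences(x)
  labels <- assign_families(seqs, threshold = threshold, method = method)
  cons <- family_consensus(seqs, labels)
  dtc <- numeric(length(seqs))
  for (f in sort(unique(labels))) {
    sel <- labels == f
    cf <- cons[[fmt_family(f)]]
    dtc[sel] <- .edit_distance_to_ref_cpp(seqs[sel], cf) /
      pmax(nchar(seqs[sel]), nchar(cf))
  }
  structure(list(labels = labels, k = length(cons), consensus = cons,
                 div_to_consensus = dtc, threshold = threshold),
            class = "hor_families")
}

#' @export
print.hor_families <- function(x, ...) {
  cat(sprintf("<hor_families> %d monomers in %d families (threshold %.3f)\n",
              length(x$labels), x$k, x$threshold))
  tab <- table(fmt_family(x$labels))
  cat("  sizes:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' Write family assignments and consensi
#'
#' `write_families_tsv()` emits one row per monomer
#' (`monomer_index`, `family_label`, `div_to_family_consensus`);
#' `write_family_consensus_fasta()` writes the per-family consensi with
#' `t<f>` headers.
#'
#' @param families an `hor_families` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_families_tsv <- function(families, path) {
  df <- data.frame(monomer_index = seq_along(families$labels) - 1L,
                   family_label = fmt_family(families$labels),
                   div_to_family_consensus = families$div_to_consensus)
  write_tsv(df, path)
}

#' @rdname write_families_tsv
#' @export
write_family_consensus_fasta <- function(families, path) {
  ss <- Biostrings::DNAStringSet(unname(families$consensus))
  names(ss) <- names(families$consensus)
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}
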