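#' Splice-site strength models
#'
#' Probabilistic models of donor and acceptor splice-site sequence in the
#' MaxEntScan window convention: donors are 9-mers (3 exonic + 6 intronic
#' bases, consensus \code{...AG|GTAAGT}), acceptors are 23-mers (20 intronic +
#' 3 exonic). Three model kinds are supported: \code{WMM}, a position weight
#' matrix with independent positions; \code{MM1}, a first-order Markov model
#' conditioning each position on the previous base; and \code{MAXENT_TABLE},
#' an externally supplied lookup of per-k-mer scores (the maximum-entropy
#' parameters themselves are published elsewhere and are loaded, never fit).
#'
#' @name splice_site_model
NULL

.window_length <- function(site_type) {
  switch(site_type, donor_5ss = 9L, acceptor_3ss = 23L,
         stop("site_type must be 'donor_5ss' or 'acceptor_3ss'"))
}

#' Train a splice-site model from aligned site windows
#'
#' @param seqs character vector of site windows, all of the exact window
#'   length for \code{site_type} (9 for donors, 23 for acceptors), ACGT only.
#' @param site_type \code{"donor_5ss"} or \code{"acceptor_3ss"}.
#' @param model_kind \code{"WMM"} or \code{"MM1"} (a \code{MAXENT_TABLE}
#'   cannot be trained; load it with \code{\link{maxent_table_model}}).
#' @param pseudocount added to every base (or conditional) count; default 0.25.
#' @param background per-base background probabilities; default uniform 0.25.
#' @return an object of class \code{splice_site_model}.
#' @export
train_model <- function(seqs, site_type = c("donor_5ss", "acceptor_3ss"),
                        model_kind = c("WMM", "MM1"), pseudocount = 0.25,
                        background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  site_type <- match.arg(site_type)
  model_kind <- match.arg(model_kind)
  L <- .window_length(site_type)
  .check(length(seqs) >= 1, "at least one training sequence required")
  .check(abs(sum(background) - 1) < 1e-9, "background must sum to 1")
  seqs <- vapply(seq_along(seqs), function(i) {
    s <- toupper(seqs[i])
    .check(nchar(s) == L, "sequence %d ('%s') is not %d nt", i, seqs[i], L)
    bad <- setdiff(unique(strsplit(s, "")[[1]]), .DNA_BASES)
    .check(length(bad) == 0, "sequence %d ('%s') has non-ACGT base(s): %s",
           i, seqs[i], paste(bad, collapse = ","))
    s
  }, character(1))
  mat <- do.call(rbind, strsplit(seqs, ""))
  n <- nrow(mat)

  # positional marginals (used by WMM, and by MM1 at position 1)
  pwm <- sapply(seq_len(L), function(j) {
    cnt <- table(factor(mat[, j], levels = .DNA_BASES))
    (as.numeric(cnt) + pseudocount) / (n + 4 * pseudocount)
  })
  rownames(pwm) <- .DNA_BASES

  cond <- NULL
  if (model_kind == "MM1") {
    # cond[[j]][prev, base]: P(base at j | base at j-1), j >= 2
    cond <- lapply(2:L, function(j) {
      m <- matrix(pseudocount, 4, 4, dimnames = list(.DNA_BASES, .DNA_BASES))
      for (i in seq_len(n)) m[mat[i, j - 1], mat[i, j]] <- m[mat[i, j - 1], mat[i, j]] + 1
      m / rowSums(m)
    })
  }

  structure(list(site_type = site_type, model_kind = model_kind,
                 window = L, pwm = pwm, cond = cond,
                 background = background[.DNA_BASES],
                 pseudocount = pseudocount, n_train = n),
            class = "splice_site_model")
}

#' Build a MAXENT_TABLE model from an external k-mer score table
#'
#' @param scores named numeric vector (names = k-mers) or data.frame with
#'   columns \code{kmer} and \code{score}, e.g. read from a published
#'   MaxEntScan score dump.
#' @param site_type \code{"donor_5ss"} or \code{"acceptor_3ss"}.
#' @return a \code{splice_site_model} of kind \code{MAXENT_TABLE}.
#' @export
maxent_table_model <- function(scores, site_type = c("donor_5ss", "acceptor_3ss")) {
  site_type <- match.arg(site_type)
  if (is.data.frame(scores)) scores <- stats::setNames(scores$score, toupper(scores$kmer))
  L <- .window_length(site_type)
  .check(all(nchar(names(scores)) == L), "all k-mers must be %d nt", L)
  structure(list(site_type = site_type, model_kind = "MAXENT_TABLE",
                 window = L, table = scores),
            class = "splice_site_model")
}

#' @export
print.splice_site_model <- function(x, ...) {
  cat(sprintf("splice_site_model: %s %s (window %d nt%s)\n",
              x$model_kind, x$site_type, x$window,
              if (x$model_kind == "MAXENT_TABLE")
                sprintf(", %d k-mers", length(x$table))
              else sprintf(", trained on %d sequence(s)", x$n_train)))
  invisible(x)
}

#' Score a site window under a splice-site model
#'
#' WMM: \code{sum_i log2(p_i(b_i) / q(b_i))}. MM1: the position-1 marginal
#' log-odds plus conditional log-odds \code{log2(p(b_i | b_{i-1}) / q(b_i))}
#' for positions >= 2. MAXENT_TABLE: the table value for the window.
#'
#' @param model a \code{splice_site_model}.
#' @param seq window sequence of the model's window length, ACGT.
#' @return numeric log2-odds score (or table score).
#' @export
score_site <- function(model, seq) {
  s <- toupper(seq)
  .check(nchar(s) == model$window, "window must be %d nt, got %d",
         model$window, nchar(s))
  bad <- setdiff(unique(strsplit(s, "")[[1]]), .DNA_BASES)
  .check(length(bad) == 0, "window has non-ACGT base(s): %s",
         paste(bad, collapse = ","))
  if (model$model_kind == "MAXENT_TABLE") {
    if (!s %in% names(model$table)) {
      stop(sprintf("table incomplete: no score for k-mer '%s'", s), call. = FALSE)
    }
    return(unname(model$table[[s]]))
  }
  b <- strsplit(s, "")[[1]]
  q <- model$background
  sc <- log2(model$pwm[b[1], 1] / q[[b[1]]])
  for (j in 2:model$window) {
    p <- if (model$model_kind == "WMM") model$pwm[b[j], j] else
      model$cond[[j - 1]][b[j - 1], b[j]]
    sc <- sc + log2(p / q[[b[j]]])
  }
  unname(sc)
}

#' Reference-versus-alternate delta score
#'
#' @param model a \code{splice_site_model}.
#' @param ref_window,alt_window site windows before and after the variant.
#' @return list with \code{ref_score}, \code{alt_score}, \code{delta}
#'   (alt - ref) and \code{interpretation} (\code{"weakened"} when delta < 0,
#'   \code{"strengthened"} when > 0, else \code{"unchanged"}).
#' @export
delta_score <- function(model, ref_window, alt_window) {
  ref_score <- score_site(model, ref_window)   # errors here before any output
  alt_score <- score_site(model, alt_window)
  d <- alt_score - ref_score
  list(ref_score = ref_score, alt_score = alt_score, delta = d,
       interpretation = if (d < 0) "weakened" else if (d > 0) "strengthened"
                        else "unchanged")
}

#' Consensus call over several model kinds
#'
#' A candidate splice variant is called splice-weakening when the delta score
#' is negative under every supplied model — the "lower efficiency under all
#' quantifications" rule.
#'
#' @param models list of \code{splice_site_model} objects of one site type.
#' @param ref_window,alt_window site windows.
#' @return list with per-model deltas and logical \code{splice_weakening}.
#' @export
splice_weakening_call <- function(models, ref_window, alt_window) {
  deltas <- vapply(models, function(m) delta_score(m, ref_window, alt_window)$delta,
                   numeric(1))
  names(deltas) <- vapply(models, function(m) m$model_kind, character(1))
  list(deltas = deltas, splice_weakening = all(deltas < 0))
}

#' Read training windows from FASTA or plain text
#'
#' @param path a FASTA file (extension .fa/.fasta) or a plain-text file with
#'   one window per line.
#' @return character vector of windows.
#' @export
read_site_windows <- function(path) {
  if (grepl("\\.(fa|fasta)$", path, ignore.case = TRUE)) {
    as.character(Biostrings::readDNAStringSet(path))
  } else {
    x <- readLines(path)
    x[nzchar(trimws(x))]
  }
}
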