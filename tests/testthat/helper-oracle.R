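# Independent brute-force class-code oracle. Works on explicit per-base
# occupancy sets (integer vectors of covered bases), delimiter-guarded
# string matching for junction chains, and a linear distance scan for
# 'p', so it shares no interval arithmetic with the package classifier.

oracle_bases <- function(exons) {
  unlist(lapply(seq_len(nrow(exons)), function(i)
    seq.int(exons[i, 1], exons[i, 2] - 1L)))
}

oracle_intron_mat <- function(exons) {
  n <- nrow(exons)
  if (n < 2L) return(cbind(start = integer(0), end = integer(0)))
  cbind(start = exons[-n, 2], end = exons[-1L, 1])
}

oracle_chain_str <- function(exons) {
  im <- oracle_intron_mat(exons)
  paste0(";", paste(paste(im[, 1], im[, 2], sep = ","), collapse = ";"), ";")
}

# contiguous sub-chain via guarded substring search
oracle_subchain <- function(inner_exons, outer_exons) {
  inner <- oracle_chain_str(inner_exons)
  if (identical(inner, ";;")) return(TRUE)
  grepl(inner, oracle_chain_str(outer_exons), fixed = TRUE)
}

# code of transfrag vs a single reference transcript, or NA
oracle_code_vs <- function(t_exons, t_strand, r) {
  same <- t_strand == "." || t_strand == r$strand
  bt <- oracle_bases(t_exons)
  br <- oracle_bases(r$exons)
  ov <- length(intersect(bt, br))
  tI <- oracle_intron_mat(t_exons)
  rI <- oracle_intron_mat(r$exons)
  t_chain <- oracle_chain_str(t_exons)
  r_chain <- oracle_chain_str(r$exons)
  junction_strs <- function(im) paste(im[, 1], im[, 2], sep = ",")

  if (same) {
    if (nrow(tI) > 0L && identical(t_chain, r_chain)) return("=")
    if (nrow(tI) == 0L && nrow(rI) == 0L &&
        ov >= 0.8 * length(bt) && ov >= 0.8 * length(br)) return("=")
    if (oracle_subchain(t_exons, r$exons) && all(bt %in% br)) return("c")
    if (oracle_subchain(r$exons, t_exons) && all(br %in% bt)) return("k")
    if (nrow(rI) > 0L && ov > 0L) {
      status <- vapply(seq_len(nrow(rI)), function(i) {
        key <- paste(rI[i, 1], rI[i, 2], sep = ",")
        if (key %in% junction_strs(tI)) return("matched")
        ib <- seq.int(rI[i, 1], rI[i, 2] - 1L)
        if (all(ib %in% bt)) return("retained")
        "no"
      }, "")
      if (all(status != "no")) return("m")
      if (any(status == "retained")) return("n")
    }
    if (nrow(tI) > 0L && nrow(rI) > 0L &&
        length(intersect(junction_strs(tI), junction_strs(rI))) > 0L)
      return("j")
    if (nrow(t_exons) == 1L && ov > 0L) {
      for (i in seq_len(nrow(rI))) {
        ib <- seq.int(rI[i, 1], rI[i, 2] - 1L)
        into <- intersect(bt, ib)
        # contiguous from a boundary shared with an overlapped exon
        touches_exon <- length(intersect(bt, br)) > 0L
        if (touches_exon && length(into) >= 10L &&
            (rI[i, 1] %in% into || (rI[i, 2] - 1L) %in% into))
          return("e")
      }
    }
    if (ov > 0L) return("o")
    for (i in seq_len(nrow(rI))) {
      ib <- seq.int(rI[i, 1], rI[i, 2] - 1L)
      if (all(bt %in% ib)) return("i")
    }
    for (i in seq_len(nrow(tI))) {
      ib <- seq.int(tI[i, 1], tI[i, 2] - 1L)
      rspan <- seq.int(r$exons[1L, 1], r$exons[nrow(r$exons), 2] - 1L)
      if (all(rspan %in% ib)) return("y")
    }
    return(NA_character_)
  }
  # opposite strand
  if (nrow(tI) > 0L && nrow(rI) > 0L &&
      length(intersect(junction_strs(tI), junction_strs(rI))) > 0L)
    return("s")
  if (ov > 0L) return("x")
  NA_character_
}

# full oracle: best code over all reference transcripts, then 'p' scan
classify_oracle <- function(t, refs) {
  order_codes <- c("=", "c", "k", "m", "n", "j", "e", "o", "s", "x",
                   "i", "y", "p", "u")
  cand <- Filter(function(r) r$chrom == t$chrom, refs$transcripts)
  codes <- vapply(cand, function(r) oracle_code_vs(t$exons, t$strand, r), "")
  codes <- codes[!is.na(codes)]
  if (length(codes) > 0L)
    return(order_codes[min(match(codes, order_codes))])
  # distance scan for 'p': walk downstream base by base from each gene end
  tb <- oracle_bases(t$exons)
  for (gi in seq_len(nrow(refs$genes))) {
    g <- refs$genes[gi, ]
    if (g$chrom != t$chrom) next
    if (t$strand != "." && g$strand != t$strand) next
    if (g$strand == "+") {
      if (min(tb) >= g$end && min(tb) - g$end <= 2000L) return("p")
    } else {
      if (max(tb) < g$start && g$start - (max(tb) + 1L) <= 2000L) return("p")
    }
  }
  "u"
}

# random toy (transfrag, reference) instance generator used by the
# oracle-equivalence suites
random_exons <- function(n, lo = 0L, hi = 3000L) {
  len <- sample(20:250, n, replace = TRUE)
  gap <- sample(20:400, n, replace = TRUE)
  start <- sample(lo:hi, 1L) + cumsum(c(0L, (len + gap)[-n]))
  exon_chain(start, start + len)
}

random_case <- function() {
  n_ref_tx <- sample(1:2, 1L)
  ref_strand <- sample(c("+", "-"), 1L)
  base <- random_exons(sample(2:4, 1L))
  refs_tx <- lapply(seq_len(n_ref_tx), function(i) {
    ex <- if (i == 1L) base else random_exons(sample(1:4, 1L))
    transcript_model(paste0("R", i), paste0("G", i), "chr1", ref_strand, ex)
  })
  refs <- annotation_set(refs_tx)

  strategy <- sample(c("independent", "jitter", "subset", "nearby",
                       "intronic", "singleexon"), 1L)
  ex <- switch(strategy,
    independent = random_exons(sample(1:3, 1L), hi = 6000L),
    jitter = {  # perturb terminal ends of the base chain, keep junctions
      e <- base
      e[1L, 1] <- max(0L, e[1L, 1] + sample(-80:80, 1L))
      e[nrow(e), 2] <- e[nrow(e), 2] + sample(-80:80, 1L)
      if (e[1L, 1] >= e[1L, 2]) e[1L, 1] <- e[1L, 2] - 10L
      if (nrow(e) > 1L && e[nrow(e), 2] <= e[nrow(e), 1])
        e[nrow(e), 2] <- e[nrow(e), 1] + 10L
      e
    },
    subset = {  # contiguous run of the base exons, trimmed inwards
      i <- sort(sample(seq_len(nrow(base)), sample(1:nrow(base), 1L)))
      i <- i[1L]:i[length(i)]
      e <- base[i, , drop = FALSE]
      e[1L, 1] <- e[1L, 1] + sample(0:10, 1L)
      e[nrow(e), 2] <- e[nrow(e), 2] - sample(0:10, 1L)
      if (e[1L, 1] >= e[1L, 2]) e[1L, 1] <- e[1L, 2] - 5L
      e
    },
    nearby = {  # single exon placed at a random offset from the gene end
      span_end <- base[nrow(base), 2]
      s <- span_end + sample(0:3000, 1L)
      exon_chain(s, s + sample(50:300, 1L))
    },
    intronic = {  # inside a gap of the base chain when one exists
      if (nrow(base) < 2L) random_exons(1L)
      else {
        i <- sample(nrow(base) - 1L, 1L)
        lo <- base[i, 2]; hi <- base[i + 1L, 1]
        w <- hi - lo
        s <- lo + sample(0:max(0L, w - 10L), 1L)
        e <- min(hi, s + sample(5:200, 1L))
        exon_chain(s, max(e, s + 1L))
      }
    },
    singleexon = {  # overlapping a random base exon, extended both ways
      i <- sample(nrow(base), 1L)
      s <- max(0L, base[i, 1] - sample(0:100, 1L))
      exon_chain(s, base[i, 2] + sample(0:100, 1L))
    })
  strand <- if (nrow(ex) == 1L) sample(c("+", "-", "."), 1L)
            else sample(c("+", "-"), 1L)
  list(t = transfrag("T1", "chr1", strand, ex), refs = refs)
}
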