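# Independent oracles and small fixture builders. Everything here is kept
# deliberately naive (set arithmetic, explicit enumeration) and shares no
# code with the package internals it checks.

# a compact locus for unit tests: exon1 101-200, intron 201-300,
# exon2 301-400 (1-based), window 10
tiny_locus <- function(window_bp = 10L) {
  normalize_locus(locus_config(
    "tiny", "chr1",
    exon1 = c(101, 200), intron1 = c(201, 300), exon2 = c(301, 400),
    window_bp = window_bp))
}

rec <- function(pos, cigar, qname = "r1", flag = 0L, mapq = 255L,
                rname = "chr1", ...) {
  alignment_records(qname = qname, flag = flag, rname = rname,
                    pos = pos, mapq = mapq, cigar = cigar, ...)
}

# minimal CIGAR walker used only by oracles
walk_cigar <- function(pos0, cigar) {
  m <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  ops <- substring(toks, nchar(toks), nchar(toks))
  lens <- as.integer(substring(toks, 1, nchar(toks) - 1L))
  aligned <- integer(0)
  skipped <- list()
  cur <- pos0
  for (i in seq_along(ops)) {
    if (ops[i] %in% c("M", "=", "X", "D")) {
      aligned <- c(aligned, seq.int(cur, length.out = lens[i]))
      cur <- cur + lens[i]
    } else if (ops[i] == "N") {
      skipped[[length(skipped) + 1L]] <- c(cur, cur + lens[i])
      cur <- cur + lens[i]
    }
    # I, S, H, P consume no reference
  }
  list(aligned = aligned, skipped = skipped)
}

# brute-force classifier: rasterize the read and apply the category rules
# by set arithmetic, first match wins
brute_classify <- function(pos0, cigar, nl,
                           exact = FALSE, min_overhang = 1L,
                           window = nl$window_bp) {
  w <- walk_cigar(pos0, cigar)
  donor <- nl$donor_site; acceptor <- nl$acceptor_site
  overhang_ok <- function(sk) {
    left <- sum((sk[1] - min_overhang):(sk[1] - 1L) %in% w$aligned) ==
      min_overhang
    right <- sum(sk[2]:(sk[2] + min_overhang - 1L) %in% w$aligned) ==
      min_overhang
    left && right
  }
  for (sk in w$skipped) {
    hit <- if (exact) sk[1] == donor && sk[2] == acceptor
           else abs(sk[1] - donor) <= window && abs(sk[2] - acceptor) <= window
    if (hit && overhang_ok(sk)) return("canonical_junction")
  }
  for (sk in w$skipped) {
    if (abs(sk[1] - donor) <= window && sk[2] > donor &&
        sk[2] < acceptor - window && overhang_ok(sk))
      return("cryptic_junction")
  }
  if (length(w$skipped) == 0L && length(w$aligned) > 0L &&
      all(w$aligned >= donor) && all(w$aligned < acceptor))
    return("intron_contained")
  "unclassified"
}

# exhaustive two-sided Fisher oracle: enumerate every table with the
# observed margins via binomial coefficients and sum the point
# probabilities not exceeding the observed one
enum_fisher_p <- function(a, b, c, d, rel_tol = 1 + 1e-7) {
  m <- a + c; n <- b + d; k <- a + b
  xs <- max(0, k - n):min(k, m)
  logp <- lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k)
  probs <- exp(logp)
  p_obs <- probs[match(a, xs)]
  min(1, sum(probs[probs <= p_obs * rel_tol]))
}

# random mapped records scattered over a tiny locus, mixing plain, spliced
# and clipped CIGARs; used by region-query and classifier property tests
random_records <- function(n, nl, seed) {
  set.seed(seed)
  pos <- sample(50:420, n, replace = TRUE)
  cigar <- character(n)
  for (i in seq_len(n)) {
    kind <- sample(5, 1)
    cigar[i] <- switch(kind,
      sprintf("%dM", sample(10:80, 1)),
      sprintf("%dM%dN%dM", sample(5:40, 1), sample(5:150, 1),
              sample(5:40, 1)),
      sprintf("%dS%dM", sample(2:10, 1), sample(10:60, 1)),
      sprintf("%dM%dD%dM", sample(5:30, 1), sample(1:5, 1),
              sample(5:30, 1)),
      sprintf("%dM%dN%dM%dN%dM", sample(3:15, 1), sample(5:60, 1),
              sample(3:15, 1), sample(5:60, 1), sample(3:15, 1)))
  }
  rec(pos = pos, cigar = cigar,
      qname = sprintf("rr%04d", seq_len(n)))
}

ref_span <- function(pos0, cigar) {
  w <- walk_cigar(pos0, cigar)
  ends <- c(w$aligned + 1L, vapply(w$skipped, `[`, numeric(1), 2))
  c(pos0, max(ends))
}

# The hand-labelled classifier truth fixture: 50 records over tiny_locus
# (donor 200, acceptor 300, window 10) covering every category and the
# boundary cases. Labels are asserted by construction and re-verified
# against brute_classify in the acceptance test.
truth_fixture <- function() {
  L <- list()
  add <- function(pos, cigar, label)
    L[[length(L) + 1L]] <<- data.frame(pos = pos, cigar = cigar,
                                       label = label,
                                       stringsAsFactors = FALSE)
  # exact canonical junction, generous overhangs
  add(150, "50M100N50M", "canonical_junction")
  # 1-base overhang on each side
  add(199, "1M100N1M", "canonical_junction")
  # windowed: skip boundaries jittered inside the +/-10 window
  add(150, "45M105N50M", "canonical_junction")   # start 195, end 300
  add(150, "55M100N50M", "canonical_junction")   # start 205, end 305
  add(150, "40M120N40M", "canonical_junction")   # start 190, end 310
  # off-by-one OUTSIDE the window: start 189 (donor-11)
  add(150, "39M121N40M", "unclassified")
  # off-by-one outside at the acceptor side: end 311
  add(150, "50M111N40M", "unclassified")
  # cryptic: donor match, acceptor deep inside the intron
  add(170, "30M50N30M", "cryptic_junction")      # skip 200-250
  add(165, "30M40N30M", "cryptic_junction")      # start 195 (window), end 235
  # cryptic boundary: acceptor at acceptor-window-1 = 289 still cryptic
  add(170, "30M89N20M", "cryptic_junction")
  # acceptor inside the acceptor window (290) -> canonical by window rule
  add(170, "30M90N20M", "canonical_junction")
  # skip start outside donor window -> neither junction, has N
  add(120, "30M50N30M", "unclassified")          # skip 150-200
  # intron-contained plain reads
  add(200, "100M", "intron_contained")
  add(210, "50M", "intron_contained")
  add(299, "1M", "intron_contained")             # last intronic base
  add(250, "20M5D20M", "intron_contained")       # D stays inside
  add(240, "10M2I10M", "intron_contained")       # insertion, 20 ref bases
  add(230, "5S30M5S", "intron_contained")        # clips consume no ref
  # ends exactly at donor: aligned [150,200) entirely exonic
  add(150, "50M", "unclassified")
  # starts exactly at acceptor
  add(300, "50M", "unclassified")
  # straddles the donor boundary without an N
  add(180, "150M", "unclassified")
  # straddles the acceptor boundary without an N
  add(280, "40M", "unclassified")
  # exon-only reads
  add(110, "50M", "unclassified")
  add(310, "60M", "unclassified")
  # multi-N: second skip is canonical (first is uninformative)
  add(160, "20M10N20M100N50M", "canonical_junction")
  # multi-N: first skip cryptic, none canonical
  add(180, "20M40N20M10N20M", "cryptic_junction")
  # multi-N: both skips uninformative
  add(100, "10M20N10M20N10M", "unclassified")
  # canonical skip but zero overhang on the right (N at read end)
  add(150, "50M100N", "unclassified")
  # D adjacent to the skip keeps the block (overhang) intact
  add(150, "45M5D100N50M", "canonical_junction")
  # soft-clipped canonical junction read
  add(195, "10S5M100N5M", "canonical_junction")
  # remaining records: bulk canonical / intron fill to 50
  for (i in 1:10) add(140 + i, sprintf("%dM100N%dM", 60 - i, 40 + i),
                      "canonical_junction")
  for (i in 1:10) add(200 + i * 3, "30M", "intron_contained")
  do.call(rbind, L)
}
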