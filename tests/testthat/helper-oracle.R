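# Independent oracles used by the unit and acceptance tests.

# Exact-rational tail summation of the phasing P-value, via Python's
# fractions module (arbitrary-precision, no floating point until the
# final conversion). Input: data.frame n, k, m, R.
exact_pvalue_oracle <- function(grid) {
  script <- paste(
    "import sys",
    "from fractions import Fraction",
    "from math import comb",
    "for line in sys.stdin:",
    "    n,k,m,R=map(int,line.split())",
    "    t=Fraction(0)",
    "    for X in range(k,min(n,m)+1):",
    "        if n-X>(R-1)*m: continue",
    "        t+=Fraction(comb((R-1)*m,n-X)*comb(m,X),comb(R*m,n))",
    "    print(repr(float(t)))",
    sep = "\n")
  inp <- sprintf("%d %d %d %d", grid$n, grid$k, grid$m, grid$R)
  out <- system2("python", c("-c", shQuote(script)), input = inp,
                 stdout = TRUE)
  as.numeric(out)
}

# Naive duplex-score oracle: exhaustive enumeration in plain R of every
# registration with zero or one single-nucleotide bulge, mirroring the
# published plant-target penalty scheme (mismatch 1, G:U 0.5, bulge 2,
# doubled at sRNA positions 2-13). Returns the minimal score, or Inf.
naive_duplex_min <- function(srna, target) {
  s <- strsplit(srna, "")[[1]]
  t <- strsplit(target, "")[[1]]
  L <- length(s); Tn <- length(t)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  pen <- function(si, ti) {
    if (identical(unname(comp[si]), ti)) return(0)
    if ((si == "G" && ti == "T") || (si == "T" && ti == "G")) return(0.5)
    1
  }
  wt <- function(i) if (i >= 2 && i <= 13) 2 else 1
  best <- Inf
  if (Tn >= L) {
    for (a in 0:(Tn - L)) {
      sc <- 0
      for (i in 1:L) sc <- sc + pen(s[i], t[a + L - i + 1]) * wt(i)
      best <- min(best, sc)
    }
  }
  if (Tn >= L + 1) {
    for (a in 0:(Tn - L - 1)) {
      for (b in 1:(L - 1)) {
        sc <- 2 * (if (b + 1 >= 2 && b + 1 <= 13) 2 else 1)
        for (i in 1:L) {
          ti <- if (i <= b) a + L + 1 - i else a + L - i
          sc <- sc + pen(s[i], t[ti + 1]) * wt(i)
        }
        best <- min(best, sc)
      }
    }
  }
  if (Tn >= L - 1) {
    for (a in 0:(Tn - (L - 1))) {
      for (b in 2:(L - 1)) {
        sc <- 2 * wt(b)
        for (i in setdiff(1:L, b)) {
          ti <- if (i < b) a + (L - 1) - i else a + L - i
          sc <- sc + pen(s[i], t[ti + 1]) * wt(i)
        }
        best <- min(best, sc)
      }
    }
  }
  best
}

# Naive exact-mapping oracle: O(L*N) scan over both strands.
naive_map_oracle <- function(read, genome) {
  hits <- list()
  rc <- phasr::revcomp(read)
  for (ref in names(genome)) {
    g <- genome[[ref]]
    L <- nchar(read)
    if (nchar(g) < L) next
    for (s in 0:(nchar(g) - L)) {
      win <- substr(g, s + 1, s + L)
      if (win == read)
        hits[[length(hits) + 1]] <- data.frame(ref_id = ref, strand = "+",
                                               start = s)
      if (win == rc)
        hits[[length(hits) + 1]] <- data.frame(ref_id = ref, strand = "-",
                                               start = s)
    }
  }
  if (length(hits) == 0)
    return(data.frame(ref_id = character(0), strand = character(0),
                      start = integer(0)))
  do.call(rbind, hits)
}
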