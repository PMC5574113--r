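# Independent brute-force oracles, kept deliberately naive so they cannot
# share a bug with the implementations they check.

# Literal simulation of the carry-down rule: walk bins from high to low,
# carrying the running surplus/deficit to the next bin and accumulating
# only positive carries.  Independent of the vectorized cumulative-sum
# implementation.
uemd_carry_oracle <- function(m, n) {
  total <- 0
  carry <- 0
  for (b in rev(seq_along(m))) {
    carry <- carry + m[b] - n[b]
    if (carry > 0) total <- total + carry
  }
  total
}

# Downward-only transport cost, simulated explicitly: walk bins from high
# to low keeping a stack of available surpluses; each deficit is served by
# the nearest surplus above it (cost = mass x bins moved).  Equals the uEMD
# whenever the tumor histogram's top-down cumulative mass dominates the
# healthy one at every bin (no deficit ever sits above a surplus), where it
# also equals the full 1-D Wasserstein distance on bin indices.
uemd_transport_oracle <- function(m, n) {
  d <- m - n
  cost <- 0
  sup_pos <- numeric(0)
  sup_mass <- numeric(0)
  for (b in rev(seq_along(d))) {
    if (d[b] > 0) {
      sup_pos <- c(sup_pos, b)
      sup_mass <- c(sup_mass, d[b])
    } else if (d[b] < 0) {
      need <- -d[b]
      while (need > 1e-15 && length(sup_pos) > 0) {
        k <- length(sup_pos)  # nearest surplus above
        take <- min(need, sup_mass[k])
        cost <- cost + take * (sup_pos[k] - b)
        sup_mass[k] <- sup_mass[k] - take
        need <- need - take
        if (sup_mass[k] <= 1e-15) {
          sup_pos <- sup_pos[-k]
          sup_mass <- sup_mass[-k]
        }
      }
    }
  }
  cost
}

# Literal double-loop version of the rank-normalization rule.
rank_normalize_oracle <- function(counts) {
  G <- length(counts)
  vapply(counts, function(x) sum(counts < x), numeric(1)) / G
}

# Random histogram on nbins bins; occasionally sparse or a point mass.
random_histogram <- function(nbins) {
  kind <- sample(3, 1)
  h <- switch(kind,
    {  # dense
      w <- runif(nbins)
      w / sum(w)
    },
    {  # sparse
      h <- numeric(nbins)
      k <- sample(nbins, sample(nbins, 1))
      w <- runif(length(k))
      h[k] <- w / sum(w)
      h
    },
    {  # point mass
      h <- numeric(nbins)
      h[sample(nbins, 1)] <- 1
      h
    })
  h
}

# Random pair (m, n) where m stochastically dominates n from the top:
# m is built from n by relocating each bin's mass to a uniform bin at or
# above its origin.
random_dominant_pair <- function(nbins) {
  n <- random_histogram(nbins)
  m <- numeric(nbins)
  for (b in seq_len(nbins)) {
    if (n[b] > 0) {
      dest <- b + sample.int(nbins - b + 1, 1) - 1  # uniform on b..nbins
      m[dest] <- m[dest] + n[b]
    }
  }
  list(m = m, n = n)
}

# Toy VCF writer for parser tests.  records: data.frame with chrom, pos,
# ref, alt, info; gts: matrix (records x individuals) of genotype strings.
write_toy_vcf <- function(records, gts, ids, path = tempfile(fileext = ".vcf")) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"g\">",
    "##INFO=<ID=VC,Number=A,Type=String,Description=\"c\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t"))
  for (i in seq_len(nrow(records))) {
    lines <- c(lines, paste(c(records$chrom[i], records$pos[i], ".",
                              records$ref[i], records$alt[i], ".", "PASS",
                              records$info[i], "GT", gts[i, ]),
                            collapse = "\t"))
  }
  writeLines(lines, path)
  path
}

write_toy_maf <- function(rows, path = tempfile(fileext = ".maf"),
                          header = "Hugo_Symbol\tTumor_Sample_Barcode\tVariant_Classification") {
  writeLines(c(header, rows), path)
  path
}
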