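test_that("RPKM follows its closed form", {
  expect_equal(compute_rpkm(10, 1000, 1e6), 10)
  expect_equal(compute_rpkm(0, 1000, 1e6), 0)
  expect_equal(compute_rpkm(250, 2500, 5e6), 20)
  m <- matrix(c(10, 250, 20, 500), 2, 2,
              dimnames = list(c("g1", "g2"), NULL))
  expect_equal(compute_rpkm(m, c(1000, 2500), c(1e6, 5e6)),
               matrix(c(10, 100, 4, 40), 2, 2,
                      dimnames = list(c("g1", "g2"), NULL)))
  expect_error(compute_rpkm(10, 0, 1e6), "lengths")
  expect_error(compute_rpkm(10, 100, 0), "library")
})

test_that("activity requires the threshold in every sample, inclusively", {
  r <- rbind(a = c(1.2, 3, 1.1, 2, 1.5),
             b = c(0.9, 3, 3, 3, 3),
             c = c(1, 1, 1, 1, 1))
  act <- classify_activity(r)
  expect_equal(unname(act), c("active", "silent", "active"))
  expect_equal(classify_activity(r[, c(3, 1, 2, 5, 4)]), act)  # order-free

  expect_error(classify_activity(r[, 1:4]), "5 samples")
  r2 <- r; r2["b", 2] <- NA
  expect_error(classify_activity(r2), "b")
})

test_that("tau hits its limits and closed-form values", {
  expect_equal(tau(c(1, 0, 0, 0)), 1)
  expect_equal(tau(rep(7, 9)), 0)
  expect_equal(tau(c(1, 0.5)), 0.5)
  expect_true(is.na(tau(c(0, 0, 0))))
  expect_error(tau(5), "2 tissues")
  expect_error(tau(c(-1, 2)), ">= 0")

  set.seed(2)
  for (i in 1:20) {
    x <- runif(8, 0, 10)
    expect_equal(tau(3.7 * x), tau(x))        # scale invariance
    # redistributing mass from the top tissue to the others (top stays
    # the maximum) cannot increase tau
    y <- x
    top <- which.max(y)
    delta <- 0.4 * (y[top] - max(y[-top]))
    y[top] <- y[top] - delta
    y[-top] <- y[-top] + delta / (length(y) - 1)
    expect_lte(tau(y), tau(x) + 1e-12)
  }
})

test_that("size categories partition the printed cut points", {
  expect_equal(as.character(gene_size_category(c(500, 999, 1000, 4000,
                                                 4001))),
               c("<1kb", "<1kb", "1-4kb", "1-4kb", ">4kb"))
  expect_equal(as.character(intron_size_category(c(60, 80, 81, 200, 201,
                                                   1000, 1001, 5000, 10000,
                                                   10001))),
               c("<=80bp", "<=80bp", "81-200bp", "81-200bp", "201bp-1kb",
                 "201bp-1kb", "1-10kb", "1-10kb", "1-10kb", ">10kb"))
})

simple_models <- function(strand = "+") {
  gene_models(
    genes = data.frame(gene_id = "g1", chrom = "chr1", strand = strand,
                       start = 1000, end = 3000),
    exons = data.frame(gene_id = "g1", start = c(1000, 2500),
                       end = c(1400, 3000)),
    cds = data.frame(gene_id = "g1", start = 1100, end = 2900))
}

test_that("gene elements derive introns, UTRs and strand-aware promoters", {
  el <- gene_elements(simple_models("+"))
  expect_equal(el[el$element == "intron", c("start", "end")],
               data.frame(start = 1400, end = 2500), ignore_attr = TRUE)
  expect_equal(el[el$element == "promoter", c("start", "end")],
               data.frame(start = 500, end = 1000), ignore_attr = TRUE)
  expect_equal(el[el$element == "utr5", c("start", "end")],
               data.frame(start = 1000, end = 1100), ignore_attr = TRUE)
  expect_equal(el[el$element == "utr3", c("start", "end")],
               data.frame(start = 2900, end = 3000), ignore_attr = TRUE)

  elm <- gene_elements(simple_models("-"))
  expect_equal(elm[elm$element == "promoter", c("start", "end")],
               data.frame(start = 3000, end = 3500), ignore_attr = TRUE)
  expect_equal(elm[elm$element == "utr5", c("start", "end")],
               data.frame(start = 2900, end = 3000), ignore_attr = TRUE)
})

test_that("element chromatin composition is exact on constructed fixtures", {
  # gene wholly inside one open domain
  doms <- data.frame(chrom = "chr1", start = c(0, 5000),
                     end = c(5000, 10000), state = c("open", "closed"))
  gm <- simple_models()
  eo <- element_overlap(doms, gm, c(g1 = "active"))
  gene_rows <- eo[eo$group == "active" & eo$element == "gene", ]
  expect_equal(gene_rows$pct[gene_rows$state == "open"], 100)

  # gene straddling the boundary at its midpoint: 50/50 by base count
  gm2 <- gene_models(
    genes = data.frame(gene_id = "g2", chrom = "chr1", strand = "+",
                       start = 4000, end = 6000),
    exons = data.frame(gene_id = "g2", start = 4000, end = 6000))
  eo2 <- element_overlap(doms, gm2, c(g2 = "active"))
  g2 <- eo2[eo2$element == "gene", ]
  expect_equal(g2$pct[g2$state == "open"], 50)
  expect_equal(g2$pct[g2$state == "closed"], 50)
  expect_equal(g2$bp[g2$state == "open"],
               per_base_overlap_bp(data.frame(start = 4000, end = 6000),
                                   data.frame(start = 0, end = 5000), 10000))

  # intergenic complement accounts for the rest of the span
  inter <- eo2[eo2$group == "intergenic", ]
  expect_equal(sum(inter$bp), 10000 - 2000)         # span minus gene span
})

test_that("degenerate activity coupling puts active genes in open chromatin", {
  cfg <- synthetic_config(genome_length = 2e6, probe_spacing = 500,
                          rng_seed = 31)
  sim <- simulate_probe_signals(cfg)
  ge <- simulate_genes_and_expression(sim$truth, cfg, n_genes = 50,
                                      coupling = 1)
  act <- classify_activity(ge$expression$rpkm)
  eo <- element_overlap(sim$truth$domains, ge$genes, act)
  act_gene <- eo[eo$group == "active" & eo$element == "gene", ]
  expect_equal(act_gene$pct[act_gene$state == "open"], 100)
})

test_that("intron profile recovers a planted edge-open structure", {
  # single 20 kb intron with an open/closed boundary at its exact centre
  doms <- data.frame(chrom = "chr1", start = c(0, 20000),
                     end = c(20000, 40000), state = c("open", "closed"))
  intr <- data.frame(chrom = "chr1", start = 10000, end = 30000)
  pr <- intron_profile(doms, intr)
  expect_equal(pr$profile5$open_fraction[1], 1)       # 5' edge open
  expect_equal(pr$profile3$open_fraction[1], 0)       # 3' edge closed
  mid <- nrow(pr$profile5)
  expect_equal(pr$profile5$open_fraction[mid], 0)     # centre closed from 5'

  # all-open introns: fraction 1, infinite ratio
  all_open <- data.frame(chrom = "chr1", start = 0, end = 40000,
                         state = "open")
  pr2 <- intron_profile(all_open, intr)
  expect_true(all(pr2$combined$open_fraction == 1))
  expect_true(all(is.infinite(pr2$combined$open_closed_ratio)))
  expect_error(intron_profile(doms, intr[0, ]), "qualifying")
})

test_that("pooled profiles decline monotonically from closed cores to open edges", {
  # introns >10 kb, open within w bp of each edge (w varies), closed middle
  widths <- rep(c(800, 1200, 1600, 2000), each = 3)
  gap <- 2000
  start <- cumsum(c(gap, head(rep(12000 + gap, length(widths)), -1)))
  intr <- data.frame(chrom = "chr1", start = start, end = start + 12000)
  doms <- list()
  cursor <- 0
  for (i in seq_along(widths)) {
    s <- intr$start[i]; e <- intr$end[i]; w <- widths[i]
    doms[[i]] <- data.frame(
      chrom = "chr1",
      start = c(cursor, s + w, e - w),
      end = c(s + w, e - w, e),
      state = c("open", "closed", "open"))
    cursor <- e
  }
  doms <- do.call(rbind, doms)
  doms <- rbind(doms, data.frame(chrom = "chr1", start = cursor,
                                 end = cursor + gap, state = "open"))
  pr <- intron_profile(doms, intr, max_offset = 59)
  for (p in list(pr$profile5, pr$profile3, pr$combined)) {
    cf <- p$closed_fraction
    expect_true(all(diff(cf) >= -1e-12))             # rises toward the core
    expect_equal(cf[1], 0)
    expect_equal(cf[length(cf)], 1)
  }
})

test_that("cluster classes match a per-base oracle and handle edge cases", {
  doms <- data.frame(chrom = "chr1", start = c(0, 1000, 2500),
                     end = c(1000, 2500, 4000),
                     state = c("open", "closed", "neutral"))
  cl <- data.frame(cluster_id = c("in_closed", "crossing", "in_open"),
                   chrom = "chr1", start = c(1100, 800, 100),
                   end = c(2400, 1200, 900))
  cc <- cluster_chromatin_class(cl, doms)
  expect_equal(cc$chromatin_class, c("closed", "mixed", "open"))
  expect_equal(as.numeric(attr(cc, "counts")), c(1, 1, 1))

  set.seed(71)
  for (rep in 1:10) {
    L <- 10000
    cuts <- sort(sample.int(L - 1, sample(3:20, 1)))
    d <- data.frame(chrom = "chr1", start = c(0, cuts), end = c(cuts, L),
                    state = sample(c("open", "closed", "neutral"),
                                   length(cuts) + 1, replace = TRUE))
    a <- sort(sample.int(L - 1, 2))
    cl2 <- data.frame(cluster_id = "c", chrom = "chr1",
                      start = a[1], end = a[2])
    got <- cluster_chromatin_class(cl2, d)$chromatin_class
    states <- unique(state_at(d, a[1]:(a[2] - 1)))
    want <- if (identical(states, "open")) "open"
            else if (identical(states, "closed")) "closed" else "mixed"
    expect_equal(got, want)
  }
})

test_that("cluster tau comparison is symmetric and honest about identity", {
  set.seed(5)
  x <- runif(30, 0.3, 0.7)
  same <- compare_cluster_tau(x, x)
  expect_equal(same$t_p, 1)
  expect_gt(same$u_p, 0.95)

  a <- runif(40, 0.3, 0.5); b <- runif(25, 0.6, 0.8)
  ab <- compare_cluster_tau(a, b)
  ba <- compare_cluster_tau(b, a)
  expect_equal(ab$t_p, ba$t_p)
  expect_equal(ab$u_p, ba$u_p)
  expect_error(compare_cluster_tau(1, c(1, 2)), ">= 2 genes")
  expect_error(compare_cluster_tau(rep(0.5, 5), rep(0.5, 5)), "degenerate")
})
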