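# Shared fixture builders. Everything is generated in code; sizes are kept
# small so the default run stays fast.

tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_individuals = 120, n_variants = 300, n_chromosomes = 2,
                   chromosome_length_bp = 1.5e6, n_qtl = 10,
                   n_cohorts = 2, cohort_sizes = c(200L, 200L),
                   missing_rate = 0, seed = 11)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# hand-built panel from an explicit dosage matrix (one chromosome, 1 kb grid)
manual_geno <- function(dosages, bp = NULL, chr = NULL) {
  m <- ncol(dosages)
  map <- data.frame(chr = chr %||% rep(1L, m),
                    bp = bp %||% (seq_len(m) * 1000L),
                    a1 = "A", a2 = "C", stringsAsFactors = FALSE)
  geno_matrix(dosages, map)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_geno <- function(n, m, seed = 1, maf = c(0.1, 0.5), missing_rate = 0) {
  set.seed(seed)
  p <- runif(m, maf[1], maf[2])
  d <- sapply(p, function(pp) rbinom(n, 2, pp))
  if (missing_rate > 0) d[runif(n * m) < missing_rate] <- NA
  storage.mode(d) <- "double"
  manual_geno(d)
}

# balanced four-factor phenotype fixture
random_pheno <- function(n = 200, seed = 3) {
  set.seed(seed)
  data.frame(
    id = sprintf("p%03d", seq_len(n)),
    trait = rnorm(n, 100, 10),
    year = sample(paste0("y", 1:4), n, replace = TRUE),
    season = sample(c("s1", "s2"), n, replace = TRUE),
    sex = sample(c("m", "f"), n, replace = TRUE),
    farm = sample(paste0("f", 1:5), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}
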