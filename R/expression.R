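#' Differential-expression configuration
#'
#' Settings for the empirical (M, D) differential-expression call:
#' fold-change and probability thresholds, the pseudocount guarding zeros,
#' the maximum size of the pooled null cloud, and the parameters of the
#' simulated-replicate null used when a strain has a single sample.
#'
#' @param lfc_threshold Minimum |log2 fold change| for a DE call (default 1).
#' @param prob_threshold Minimum noise-dominance probability (default 0.8).
#' @param k Pseudocount added to normalized means (default 0.5).
#' @param null_size Maximum number of null (M, D) points retained
#'   (default 1e5; larger clouds are subsampled, seeded).
#' @param seed Integer seed for any resampling.
#' @param pnr Fraction of a sample's depth drawn per simulated pseudo-replicate.
#' @param nss Number of pseudo-replicates per sample for the simulated null.
#' @return A list of class `de_config`.
#' @export
de_config <- function(lfc_threshold = 1, prob_threshold = 0.8, k = 0.5,
                      null_size = 1e5, seed = 1L, pnr = 0.2, nss = 5L) {
  stopifnot(lfc_threshold >= 0, prob_threshold >= 0, k > 0, null_size >= 1,
            pnr > 0, pnr <= 1, nss >= 2)
  structure(list(lfc_threshold = lfc_threshold,
                 prob_threshold = prob_threshold, k = k,
                 null_size = as.integer(null_size), seed = as.integer(seed),
                 pnr = pnr, nss = as.integer(nss)),
            class = "de_config")
}

check_count_matrix <- function(counts, samples, lengths) {
  stopifnot("gene_id" %in% names(counts),
            all(c("sample_id", "strain") %in% names(samples)),
            all(c("gene_id", "length_bp") %in% names(lengths)))
  missing <- setdiff(samples$sample_id, names(counts))
  if (length(missing)) {
    stop("sample(s) missing from count table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(counts[, samples$sample_id, drop = FALSE])
  if (any(m < 0)) stop("negative counts", call. = FALSE)
  len <- lengths$length_bp[match(counts$gene_id, lengths$gene_id)]
  if (anyNA(len) || any(len <= 0)) {
    stop("every gene needs a positive length", call. = FALSE)
  }
  list(m = m, gene_id = counts$gene_id, len = len)
}

#' FPKM normalization
#'
#' Fragments per kilobase of exon per million mapped fragments:
#' `count * 1e9 / (length_bp * sample_total)`.
#'
#' @param counts Tibble with a `gene_id` column and one integer column per
#'   sample.
#' @param lengths Tibble with `gene_id` and `length_bp` columns.
#' @return Tibble of the same shape with FPKM values.
#' @export
fpkm <- function(counts, lengths) {
  sample_cols <- setdiff(names(counts), "gene_id")
  chk <- check_count_matrix(counts, tibble(sample_id = sample_cols,
                                           strain = "x"), lengths)
  totals <- colSums(chk$m)
  if (any(totals == 0)) {
    stop("sample(s) with zero total count: ",
         paste(sample_cols[totals == 0], collapse = ", "), call. = FALSE)
  }
  vals <- sweep(chk$m * 1e9 / chk$len, 2L, totals, "/")
  dplyr::bind_cols(tibble(gene_id = counts$gene_id), as_tibble(vals))
}

# pooled null (M, D) cloud from within-strain replicate pairs
replicate_null <- function(norm, samples, strains, k) {
  Mn <- Dn <- numeric(0)
  for (s in strains) {
    ids <- samples$sample_id[samples$strain == s]
    if (length(ids) < 2L) next
    prs <- utils::combn(ids, 2L)
    for (j in seq_len(ncol(prs))) {
      a <- norm[, prs[1L, j]]
      b <- norm[, prs[2L, j]]
      Mn <- c(Mn, log2((a + k) / (b + k)))
      Dn <- c(Dn, abs(a - b))
    }
  }
  tibble(M = Mn, D = Dn)
}

# simulated null: multinomial pseudo-replicates of each sample
simulated_null <- function(m, len, samples, cfg) {
  Mn <- Dn <- numeric(0)
  for (s in samples$sample_id) {
    x <- m[, s]
    total <- sum(x)
    size <- max(1L, round(cfg$pnr * total))
    reps <- rmultinom(cfg$nss, size, prob = x / total)
    norm <- sweep(reps * 1e9 / len, 2L, colSums(reps), "/")
    prs <- utils::combn(seq_len(cfg$nss), 2L)
    for (j in seq_len(ncol(prs))) {
      a <- norm[, prs[1L, j]]
      b <- norm[, prs[2L, j]]
      Mn <- c(Mn, log2((a + cfg$k) / (b + cfg$k)))
      Dn <- c(Dn, abs(a - b))
    }
  }
  tibble(M = Mn, D = Dn)
}

#' Call differential expression with the empirical (M, D) statistic
#'
#' For each gene, M is the log2 ratio and D the absolute difference of the
#' pseudocounted mean FPKM between the two strains (strain 2 over strain 1,
#' in order of appearance in `samples`). A pooled null (M, D) cloud is built
#' from all within-strain replicate pairs when both strains have replicates,
#' otherwise from seeded multinomial pseudo-replicates of each sample. The
#' probability of a gene is the fraction of null points it strictly
#' dominates (|M_null| < |M| and D_null < D); ties count against the gene.
#'
#' @param counts Tibble: `gene_id` plus one column per sample.
#' @param samples Tibble: `sample_id`, `strain` (exactly two strains).
#' @param lengths Tibble: `gene_id`, `length_bp`.
#' @param config A [de_config()].
#' @return A `de_result` tibble: `gene_id`, `M`, `D`, `probability`,
#'   `is_de`; the null cloud, strain order and configuration are attached as
#'   attributes.
#' @export
de_call <- function(counts, samples, lengths, config = de_config()) {
  samples <- as_tibble(samples)
  strains <- unique(samples$strain)
  if (length(strains) != 2L) stop("exactly two strains required", call. = FALSE)
  if (nrow(samples) < 2L) stop("at least two samples required", call. = FALSE)
  chk <- check_count_matrix(counts, samples, lengths)
  norm_tbl <- fpkm(counts[, c("gene_id", samples$sample_id)], lengths)
  norm <- as.matrix(norm_tbl[, samples$sample_id, drop = FALSE])
  rownames(norm) <- counts$gene_id
  k <- config$k
  s1 <- samples$sample_id[samples$strain == strains[1]]
  s2 <- samples$sample_id[samples$strain == strains[2]]
  x1 <- rowMeans(norm[, s1, drop = FALSE]) + k
  x2 <- rowMeans(norm[, s2, drop = FALSE]) + k
  M <- log2(x2 / x1)
  D <- abs(x2 - x1)
  have_reps <- length(s1) >= 2L && length(s2) >= 2L
  null <- withr::with_seed(config$seed, {
    nl <- if (have_reps) {
      replicate_null(norm, samples, strains, k)
    } else {
      simulated_null(chk$m, chk$len, samples, config)
    }
    if (nrow(nl) > config$null_size) {
      nl[sample.int(nrow(nl), config$null_size), ]
    } else nl
  })
  abs_Mn <- abs(null$M)
  Dn <- null$D
  probability <- vapply(seq_along(M), function(g) {
    mean(abs_Mn < abs(M[g]) & Dn < D[g])
  }, numeric(1))
  res <- tibble(
    gene_id = counts$gene_id, M = unname(M), D = unname(D),
    probability = probability,
    is_de = abs(M) >= config$lfc_threshold &
      probability >= config$prob_threshold
  )
  structure(res, class = c("de_result", class(res)),
            config = config, null = null, strains = strains,
            null_type = if (have_reps) "replicate" else "simulated")
}

#' @exportS3Method generics::tidy
tidy.de_result <- function(x, ...) {
  as_tibble(unclass(x)[c("gene_id", "M", "D", "probability", "is_de")])
}

#' @exportS3Method generics::glance
glance.de_result <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble(
    n_genes = nrow(x),
    n_de = sum(x$is_de),
    n_up = sum(x$is_de & x$M > 0),
    n_down = sum(x$is_de & x$M < 0),
    null_points = nrow(attr(x, "null")),
    null_type = attr(x, "null_type"),
    lfc_threshold = cfg$lfc_threshold,
    prob_threshold = cfg$prob_threshold
  )
}

#' MD plot of a differential-expression result
#'
#' Gene (M, D) points over the pooled null cloud; DE calls highlighted.
#'
#' @param object A `de_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.de_result <- function(object, ...) {
  null <- attr(object, "null")
  genes <- tidy(object)
  ggplot2::ggplot() +
    ggplot2::geom_point(data = null,
                        ggplot2::aes(x = .data$M, y = log10(.data$D + 1)),
                        colour = "grey80", size = 0.5) +
    ggplot2::geom_point(data = genes,
                        ggplot2::aes(x = .data$M, y = log10(.data$D + 1),
                                     colour = .data$is_de), size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "M (log2 fold change)", y = "log10(D + 1)",
                  colour = "DE call") +
    ggplot2::theme_minimal()
}

#' Genes altered at least twofold
#'
#' The fold-change-only filter (`|M| >= lfc`, probability not required) used
#' when asking whether variant-bearing genes change expression.
#'
#' @param results A `de_result` or tibble with `gene_id` and `M`.
#' @param lfc Fold-change threshold on the log2 scale (default 1; the
#'   boundary is included).
#' @return Sorted character vector of gene ids.
#' @export
twofold_set <- function(results, lfc = 1) {
  sort(results$gene_id[abs(results$M) >= lfc])
}

#' Read a count table
#'
#' @param path TSV with a `gene_id` column and one column per sample.
#' @return Tibble.
#' @export
read_counts <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Read a sample-to-strain map
#'
#' @param path Two-column TSV `sample_id`, `strain`.
#' @return Tibble.
#' @export
read_sample_map <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(.default = readr::col_character()))
}

#' Read gene lengths
#'
#' @param path Two-column TSV `gene_id`, `length_bp`.
#' @return Tibble.
#' @export
read_gene_lengths <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write a differential-expression result table
#'
#' @param results A `de_result`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_de_results <- function(results, path) {
  readr::write_tsv(tidy(results), path)
  invisible(path)
}
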