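#' @name synthdata
#' @title Synthetic multi-dataset degradability generator
#'
#' @description
#' Emulates the premise of the integration method: several datasets each
#' observe a monotone, condition-distorted, noisy view of one common latent
#' degradability. Surrogate polymers carry synthetic 300-dimensional
#' fingerprints; the latent score is s = w_true . x; dataset j reports
#' g_j(s) + noise, shifted to be non-negative. Because the ranking method
#' only consumes within-dataset order, the per-dataset shift is harmless.
NULL

make_transform <- function(label) {
  if (label == "identity") return(function(u) u)
  if (label == "log1p") return(function(u) sign(u) * log1p(3 * abs(u)))
  if (grepl("^power:", label)) {
    g <- as.numeric(sub("^power:", "", label))
    if (!is.finite(g) || g <= 0) stop("bad power transform: ", label, call. = FALSE)
    return(function(u) sign(u) * abs(u)^g)
  }
  if (grepl("^affine:", label)) {
    ab <- as.numeric(strsplit(sub("^affine:", "", label), ",")[[1]])
    if (length(ab) != 2 || !all(is.finite(ab)) || ab[2] <= 0) {
      stop("bad affine transform: ", label, call. = FALSE)
    }
    return(function(u) ab[1] + ab[2] * u)
  }
  stop("unknown transform label: ", label, call. = FALSE)
}

#' Configuration for the synthetic generator
#'
#' @param n_polymers polymers per dataset (scalar or one per dataset).
#' @param n_datasets number of datasets.
#' @param transforms monotone transform label per dataset: `"identity"`,
#'   `"log1p"`, `"power:<gamma>"` or `"affine:<a>,<b>"`. Recycled.
#' @param noise_sd Gaussian observation noise per dataset, on the scale of
#'   the (unit-variance) latent score. Recycled.
#' @param overlap polymers shared between consecutive dataset pairs.
#' @param w_true optional latent weight vector (length 300); default drawn
#'   from the seed.
#' @param smiles_source `"placeholder"` (surrogate ids, no chemistry) or
#'   `"fixtures"` (repeat-unit SMILES drawn from the packaged tables, so the
#'   full chemistry path can be exercised).
#' @param seed integer seed; fixed seed gives bit-reproducible output.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_polymers = 20L, n_datasets = 3L,
                         transforms = c("identity", "log1p", "power:1.5"),
                         noise_sd = 0.05, overlap = 0L, w_true = NULL,
                         smiles_source = c("placeholder", "fixtures"),
                         seed = 1L) {
  smiles_source <- match.arg(smiles_source)
  n_polymers <- rep_len(as.integer(n_polymers), n_datasets)
  transforms <- rep_len(transforms, n_datasets)
  noise_sd <- rep_len(as.numeric(noise_sd), n_datasets)
  if (any(noise_sd < 0)) stop("noise_sd must be >= 0", call. = FALSE)
  if (overlap < 0 || any(overlap >= n_polymers)) {
    stop("overlap must satisfy 0 <= overlap < n_polymers", call. = FALSE)
  }
  for (tr in transforms) make_transform(tr)  # validate labels now
  structure(list(n_polymers = n_polymers, n_datasets = as.integer(n_datasets),
                 transforms = transforms, noise_sd = noise_sd,
                 overlap = as.integer(overlap), w_true = w_true,
                 smiles_source = smiles_source, seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate synthetic degradability datasets with known latent structure
#'
#' @param config a [synth_config()].
#' @return list with `datasets` (list of [degradation_dataset()], each
#'   carrying its fingerprint matrix as attribute `fingerprints`),
#'   `ground_truth` (data.frame of polymer id and latent score, one row per
#'   distinct polymer) and `w_true`.
#' @export
generate_synth <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_polymers
  k <- config$n_datasets
  ov <- config$overlap
  starts <- cumsum(c(1L, utils::head(n, -1) - ov))
  total <- starts[k] + n[k] - 1L
  with_seed(config$seed, {
    if (config$smiles_source == "fixtures") {
      fx <- paper_fixtures()
      pool_smiles <- unique(unlist(lapply(fx, function(d) d$records$smiles)))
      if (total > length(pool_smiles)) {
        stop("fixtures mode supports at most ", length(pool_smiles),
             " distinct polymers", call. = FALSE)
      }
      smiles <- sample(pool_smiles, total)
      X <- fingerprint_polymers(smiles)
    } else {
      smiles <- sprintf("SYN-%04d", seq_len(total))
      X <- matrix(stats::rnorm(total * FINGERPRINT_DIM), total,
                  FINGERPRINT_DIM)
      attr(X, "scheme_id") <- "synthetic"
    }
    w_true <- config$w_true
    if (is.null(w_true)) {
      w_true <- stats::rnorm(FINGERPRINT_DIM) / sqrt(FINGERPRINT_DIM)
    }
    s <- as.numeric(X %*% w_true)
    s_std <- (s - mean(s)) / stats::sd(s)
    datasets <- vector("list", k)
    for (j in seq_len(k)) {
      idx <- seq(starts[j], length.out = n[j])
      g <- make_transform(config$transforms[j])
      raw <- g(s_std[idx]) + stats::rnorm(n[j], sd = config$noise_sd[j])
      rec <- data.frame(
        name = sprintf("synthetic polymer %d", idx),
        abbreviation = sprintf("P%04d", idx),
        smiles = smiles[idx],
        value = raw - min(raw),  # per-dataset shift; order untouched
        stringsAsFactors = FALSE
      )
      ds <- degradation_dataset(rec, id = sprintf("synth%d", j),
                                units = "arbitrary",
                                canonicalize = config$smiles_source == "fixtures")
      Xj <- X[idx, , drop = FALSE]
      attr(Xj, "scheme_id") <- attr(X, "scheme_id")
      attr(ds, "fingerprints") <- Xj
      datasets[[j]] <- ds
    }
    list(datasets = datasets,
         ground_truth = data.frame(polymer = sprintf("P%04d", seq_len(total)),
                                   smiles = smiles,
                                   latent = s, stringsAsFactors = FALSE),
         w_true = w_true,
         fingerprints = X)
  })
}

#' The three packaged degradability datasets
#'
#' Verified copies of the published tables: the literature dataset (24
#' polymers ranked by weight loss per day), exposure experiment 1 (7 polymer
#' films with full measurement columns and delta) and exposure experiment 2
#' (8 commercial films; delta only, as the printed measurement columns are
#' not machine-recoverable). Attachment-point typography is normalized on
#' ingestion.
#'
#' @return named list of three [degradation_dataset()] objects
#'   (`literature`, `exp1`, `exp2`).
#' @export
paper_fixtures <- function() {
  dir <- system.file("extdata", package = "polyrank")
  list(
    literature = read_dataset(file.path(dir, "literature.tsv"), "literature",
                              column_map = list(smiles = "smiles",
                                                value = "value",
                                                name = "name",
                                                abbreviation = "abbreviation"),
                              units = "%/day"),
    exp1 = read_dataset(file.path(dir, "exp1.tsv"), "exp1",
                        column_map = list(smiles = "smiles", value = "value",
                                          name = "name",
                                          abbreviation = "abbreviation"),
                        units = "delta"),
    exp2 = read_dataset(file.path(dir, "exp2.tsv"), "exp2",
                        column_map = list(smiles = "smiles", value = "value",
                                          name = "name",
                                          abbreviation = "abbreviation"),
                        units = "delta")
  )
}
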