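#' @name featurize
#' @title Molecular featurization for polymer repeat units
#'
#' @description
#' Two featurizations are provided. `fingerprint_polymers()` computes the
#' 300-dimensional vector consumed by the ranking model: by default a
#' deterministic hashed atom-environment fingerprint (each atom contributes
#' its radius-0 and radius-1 environment identifier to a hash bucket; the
#' molecule is the sum over atoms, the same sum-of-substructure-vectors shape
#' as unsupervised substructure embeddings such as Mol2vec). An embedding
#' table can be supplied to replace the hashed buckets with learned vectors.
#' `count_descriptors()` computes the nine functional-group counts used for
#' factor analysis of the learned scores.
NULL

FINGERPRINT_DIM <- 300L

#' Names of the nine functional-group descriptors, in canonical order
#' @export
descriptor_names <- function() {
  c("ester", "alkyl_carbon", "hydroxyl", "ether", "benzene_ring",
    "amide", "carbonate", "heteroatom", "urethane")
}

# Deterministic polynomial string hash (Horner, modulus 2^31 - 1). All
# arithmetic stays below 2^53 so the result is exact in doubles.
string_hash <- function(s, seed = 17L) {
  p <- 2147483647
  h <- as.double(seed)
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% p
  h
}

# Atom-environment identifier strings for one parsed molecule: radius 0 is
# (element, heavy degree, summed bond order); radius 1 appends the sorted
# (bond order, neighbor radius-0) tokens. Wildcard atoms carry the literal
# "*" marker so the polymerization point is encoded, as it is in the SMILES.
atom_environments <- function(graph) {
  n <- length(graph$elements)
  b <- graph$bonds
  deg <- tabulate(c(b[, 1], b[, 2]), nbins = n)
  bsum <- numeric(n)
  if (nrow(b)) {
    for (k in seq_len(nrow(b))) {
      bsum[b[k, 1]] <- bsum[b[k, 1]] + b[k, 3]
      bsum[b[k, 2]] <- bsum[b[k, 2]] + b[k, 3]
    }
  }
  id0 <- sprintf("%s;%d;%d", graph$elements, deg, bsum)
  id1 <- vapply(seq_len(n), function(i) {
    rows <- which(b[, 1] == i | b[, 2] == i)
    if (!length(rows)) return(paste0(id0[i], "|"))
    nbr <- ifelse(b[rows, 1] == i, b[rows, 2], b[rows, 1])
    tok <- sort(sprintf("%d:%s", b[rows, 3], id0[nbr]))
    paste0(id0[i], "|", paste(tok, collapse = ","))
  }, character(1))
  list(id0 = id0, id1 = id1,
       wildcard = graph$elements %in% WILDCARD_SYMBOLS)
}

hash_environments <- function(env, hash_seed = 17L) {
  v <- numeric(FINGERPRINT_DIM)
  # bucket 1 is reserved for the radius-0 wildcard marker; everything else is
  # hashed into buckets 2..300
  bucket <- function(s) 2L + (string_hash(s, hash_seed) %% (FINGERPRINT_DIM - 1L))
  for (i in seq_along(env$id0)) {
    b0 <- if (env$wildcard[i]) 1L else bucket(env$id0[i])
    v[b0] <- v[b0] + 1
    b1 <- bucket(env$id1[i])
    v[b1] <- v[b1] + 1
  }
  v
}

embed_environments <- function(env, table) {
  v <- numeric(FINGERPRINT_DIM)
  for (id in c(env$id0, env$id1)) {
    row <- table[[id]]
    if (!is.null(row)) v <- v + row   # unknown identifiers contribute zero
  }
  v
}

#' Read a substructure-embedding table
#'
#' Tab-separated file with a column `identifier` followed by 300 numeric
#' columns. Identifiers are atom-environment strings as produced internally
#' (see [fingerprint_polymers()]); unknown identifiers encountered at
#' featurization time contribute the zero vector.
#'
#' @param path path to the TSV.
#' @return named list of numeric vectors, one per identifier.
#' @export
read_embedding_table <- function(path) {
  if (!file.exists(path)) {
    stop("embedding table not found: ", path, call. = FALSE)
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!"identifier" %in% names(tab) || ncol(tab) != FINGERPRINT_DIM + 1L) {
    stop("embedding table needs 'identifier' + ", FINGERPRINT_DIM,
         " numeric columns", call. = FALSE)
  }
  mat <- as.matrix(tab[, setdiff(names(tab), "identifier")])
  out <- lapply(seq_len(nrow(mat)), function(i) as.numeric(mat[i, ]))
  names(out) <- tab$identifier
  out
}

#' Fingerprint polymer repeat units
#'
#' @param smiles character vector of repeat-unit SMILES (wildcard `*`
#'   attachment points allowed). SMILES are canonicalized before
#'   featurization, so any spelling of the same graph yields the same vector.
#' @param scheme `"default-hashed"` (deterministic, no external data) or
#'   `"embedding-table"` (requires `embedding_table`).
#' @param embedding_table a table from [read_embedding_table()], or a path.
#' @param hash_seed integer seed folded into the hash (fixed default; part of
#'   the scheme identity).
#' @return numeric matrix, one row per input SMILES, 300 columns; attribute
#'   `scheme_id` records the featurization configuration.
#' @export
fingerprint_polymers <- function(smiles, scheme = c("default-hashed",
                                                    "embedding-table"),
                                 embedding_table = NULL, hash_seed = 17L) {
  scheme <- match.arg(scheme)
  if (scheme == "embedding-table") {
    if (is.character(embedding_table)) {
      embedding_table <- read_embedding_table(embedding_table)
    }
    if (!is.list(embedding_table)) {
      stop("scheme 'embedding-table' requires an embedding table",
           call. = FALSE)
    }
  }
  can <- canonicalize_smiles(smiles)
  X <- t(vapply(can, function(s) {
    env <- atom_environments(parse_molecule(s))
    if (scheme == "default-hashed") {
      hash_environments(env, hash_seed = hash_seed)
    } else {
      embed_environments(env, embedding_table)
    }
  }, numeric(FINGERPRINT_DIM)))
  rownames(X) <- NULL
  attr(X, "scheme_id") <- if (scheme == "default-hashed") {
    sprintf("default-hashed/seed=%d", as.integer(hash_seed))
  } else {
    "embedding-table"
  }
  X
}

# SMARTS used for the nine descriptors. Ester requires carbon on both sides
# of the O-C(=O) linkage, which excludes carbonates (O on the acyl side) and
# urethanes (N on the acyl side). Ether oxygens must bridge two non-carbonyl
# carbons, excluding ester/carbonate/urethane oxygens; acetal oxygens count.
DESCRIPTOR_SMARTS <- list(
  ester = "[#6][OX2][CX3](=[OX1])[#6]",
  alkyl_carbon = "[CX4]",
  hydroxyl = "[OX2H]",
  ether = "[OX2]([#6;!$([CX3]=[OX1])])[#6;!$([CX3]=[OX1])]",
  benzene_ring = "c1ccccc1",
  amide_all = "[NX3][CX3]=[OX1]",
  carbonate = "[OX2][CX3](=[OX1])[OX2]",
  heteroatom = "[!#6;!#1]",
  urethane = "[NX3][CX3](=[OX1])[OX2]"
)

#' Count the nine functional-group descriptors of a repeat unit
#'
#' Counts are evaluated on the closed repeat unit: the two attachment points
#' are joined so that linkages split across the polymerization point (the
#' ester of polylactide, the amide of a polyamide, ...) are counted exactly
#' once per repeat unit. Benzene rings are six-membered all-carbon aromatic
#' rings (a naphthalene unit counts two); alkyl carbons are sp3 carbons;
#' heteroatoms are all atoms that are neither carbon nor hydrogen (wildcards
#' excluded).
#'
#' @param smiles character vector of repeat-unit SMILES.
#' @return data.frame with one row per input and the nine integer columns of
#'   [descriptor_names()].
#' @export
count_descriptors <- function(smiles) {
  smiles <- normalize_smiles_typography(smiles)
  rows <- lapply(smiles, function(s) {
    g <- close_repeat_unit(s)
    raw <- vapply(DESCRIPTOR_SMARTS, function(q) count_smarts(g, q),
                  numeric(1))
    raw <- raw / g$scale
    counts <- c(
      ester = raw[["ester"]],
      alkyl_carbon = raw[["alkyl_carbon"]],
      hydroxyl = raw[["hydroxyl"]],
      ether = raw[["ether"]],
      benzene_ring = raw[["benzene_ring"]],
      amide = raw[["amide_all"]] - raw[["urethane"]],
      carbonate = raw[["carbonate"]],
      heteroatom = raw[["heteroatom"]],
      urethane = raw[["urethane"]]
    )
    if (any(counts < 0) || any(abs(counts - round(counts)) > 1e-9)) {
      stop("descriptor counting produced a non-integer count for '", s, "'",
           call. = FALSE)
    }
    counts
  })
  out <- as.data.frame(do.call(rbind, rows))
  out[] <- lapply(out, as.integer)
  names(out) <- descriptor_names()
  out
}
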