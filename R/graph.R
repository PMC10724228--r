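# Internal molecular-graph helpers built on ChemmineR/ChemmineOB.
# A parsed molecule is a list(elements, bonds) where bonds is a matrix with
# columns (a, b, order) indexing into elements. Wildcard attachment points
# keep their "*" element symbol.

WILDCARD_SYMBOLS <- c("*", "R", "Du")

parse_molecule <- function(smiles) {
  smiles <- normalize_smiles_typography(smiles)
  sdf <- try(suppressWarnings(ChemmineR::smiles2sdf(smiles)), silent = TRUE)
  if (inherits(sdf, "try-error")) {
    stop("SMILES failed to parse: '", smiles, "'", call. = FALSE)
  }
  sdf_to_graph(sdf[[1]])
}

sdf_to_graph <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- gsub("_.*$", "", rownames(ab))
  bonds <- if (is.null(bb) || nrow(bb) == 0) {
    matrix(numeric(0), 0, 3)
  } else {
    unname(cbind(bb[, 1], bb[, 2], bb[, 3]))
  }
  list(elements = elements, bonds = bonds, sdf = sdf)
}

graph_neighbors <- function(graph, i) {
  b <- graph$bonds
  c(b[b[, 1] == i, 2], b[b[, 2] == i, 1])
}

# Close a repeat unit into a "dimer ring": remove the two wildcard atoms,
# duplicate the remaining unit, and bond the attachment neighbors
# head-to-tail in both directions. Every linkage split across the attachment
# points (ester, amide, urethane, ...) then appears as an intact group, twice;
# substructure counts on the dimer are exactly twice the per-unit counts.
# Units with != 2 wildcards are returned star-stripped without closure.
close_repeat_unit <- function(smiles) {
  g <- parse_molecule(smiles)
  stars <- which(g$elements %in% WILDCARD_SYMBOLS)
  n <- length(g$elements)
  keep <- setdiff(seq_len(n), stars)
  if (length(keep) == 0) stop("repeat unit has no real atoms", call. = FALSE)
  map <- match(seq_len(n), keep)
  bb <- g$bonds
  in_unit <- !(bb[, 1] %in% stars | bb[, 2] %in% stars)
  bbk <- bb[in_unit, , drop = FALSE]
  if (nrow(bbk)) {
    bbk[, 1] <- map[bbk[, 1]]
    bbk[, 2] <- map[bbk[, 2]]
  }
  m <- length(keep)
  closable <- FALSE
  if (length(stars) == 2) {
    nb <- lapply(stars, function(i) setdiff(unique(graph_neighbors(g, i)), stars))
    closable <- all(lengths(nb) == 1)
  }
  if (closable) {
    a <- map[nb[[1]]]
    b <- map[nb[[2]]]
    elements <- c(g$elements[keep], g$elements[keep])
    bbk2 <- bbk
    if (nrow(bbk2)) bbk2[, 1:2] <- bbk2[, 1:2] + m
    bonds <- rbind(bbk, bbk2, c(a, b + m, 1), c(b, a + m, 1))
    # degenerate single-atom backbones give the same cross bond twice
    key <- paste(pmin(bonds[, 1], bonds[, 2]), pmax(bonds[, 1], bonds[, 2]))
    bonds <- bonds[!duplicated(key), , drop = FALSE]
    scale <- 2L
  } else {
    elements <- g$elements[keep]
    bonds <- bbk
    scale <- 1L
  }
  list(elements = elements, bonds = bonds, scale = scale)
}

# Build an in-memory SDFset from an element/bond list (for SMARTS matching).
graph_to_sdfset <- function(elements, bonds, id = "mol") {
  n <- length(elements)
  # 15 numeric columns = coordinates + the MDL atom-line flag fields that
  # ChemmineR's molblock writer expects
  ab <- matrix(0, n, 15,
               dimnames = list(paste(elements, seq_len(n), sep = "_"),
                               c("C1", "C2", "C3", paste0("C", 5:16))))
  nb <- nrow(bonds)
  bbl <- matrix(0, nb, 3, dimnames = list(seq_len(max(nb, 0)),
                                          c("C1", "C2", "C3")))
  if (nb) bbl[, 1:3] <- bonds[, 1:3]
  header <- c(
    Molecule_Name = id,
    Source = "polyrank",
    Comment = "",
    Counts_Line = sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb)
  )
  sdf <- methods::new("SDF", header = header, atomblock = ab,
                      bondblock = bbl, datablock = character(0))
  methods::new("SDFset", SDF = list(sdf), ID = id)
}

# Count unique SMARTS matches on an element/bond list.
count_smarts <- function(graph, smarts) {
  sdfset <- graph_to_sdfset(graph$elements, graph$bonds)
  as.numeric(ChemmineR::smartsSearchOB(sdfset, smarts, uniqueMatches = TRUE))
}
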