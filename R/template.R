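# Fibril template: stacked cross-beta backbone used as the threading scaffold.

#' Construct a fibril template
#'
#' A fibril template is an ordered stack of identical chains (layers) of a
#' cross-beta fibril, represented by per-residue CA coordinates plus CB
#' coordinates for non-glycine residues.  Layers must already be in stacking
#' order; [read_template()] orders them geometrically when reading a PDB.
#'
#' @param id Free-text identifier.
#' @param template_seq One-letter sequence of a single layer.
#' @param ca Numeric array `[n_layers, n_res, 3]` of CA coordinates
#'   (Angstrom).
#' @param cb Numeric array `[n_layers, n_res, 3]` of CB coordinates; rows for
#'   glycine are `NA`.
#' @return Object of class `fibril_template`.
#' @export
fibril_template <- function(id, template_seq, ca, cb) {
  template_seq <- validate_seq(template_seq, id)
  n_res <- nchar(template_seq)
  stopifnot(is.array(ca), length(dim(ca)) == 3L, dim(ca)[3] == 3L)
  n_layers <- dim(ca)[1]
  tpl <- structure(
    list(
      id = id,
      template_seq = template_seq,
      n_layers = n_layers,
      n_res = n_res,
      ca = ca,
      cb = cb
    ),
    class = "fibril_template"
  )
  validate_template(tpl)
}

# Enforce the full type invariant set; returns the template invisibly-valid.
validate_template <- function(tpl) {
  if (tpl$n_layers < 4L) {
    stop_validation(
      "template '", tpl$id, "' has ", tpl$n_layers,
      " chains; at least 4 are required to thread a heterotetramer"
    )
  }
  dca <- dim(tpl$ca)
  dcb <- dim(tpl$cb)
  if (!identical(dca, c(tpl$n_layers, tpl$n_res, 3L)) ||
      !identical(dcb, dca)) {
    stop_validation("template '", tpl$id, "' coordinate arrays malformed")
  }
  if (anyNA(tpl$ca)) {
    stop_validation("template '", tpl$id, "' has residues without CA atoms")
  }
  res <- seq_chars(tpl$template_seq)
  non_gly <- which(res != "G")
  if (length(non_gly)) {
    cb_ok <- !apply(is.na(tpl$cb[, non_gly, , drop = FALSE]), c(1, 2), any)
    if (!all(cb_ok)) {
      stop_validation(
        "template '", tpl$id, "' missing CB for non-glycine residue(s)"
      )
    }
  }
  for (l in seq_len(tpl$n_layers)) {
    xyz <- tpl$ca[l, , , drop = TRUE]
    d <- sqrt(rowSums((xyz[-1, , drop = FALSE] -
                         xyz[-tpl$n_res, , drop = FALSE])^2))
    if (any(d < 2.8 | d > 4.5)) {
      stop_validation(
        "template '", tpl$id, "' layer ", l,
        ": consecutive CA-CA distance outside [2.8, 4.5] Angstrom"
      )
    }
  }
  tpl
}

#' @export
print.fibril_template <- function(x, ...) {
  cat(sprintf(
    "<fibril_template> %s: %d layers x %d residues\n  %s\n",
    x$id, x$n_layers, x$n_res, x$template_seq
  ))
  invisible(x)
}

#' Read a fibril template from a PDB file
#'
#' Reads a classic fixed-column PDB structure with at least four chains of
#' equal length and identical residue ordering, and returns a
#' [fibril_template()].  Hetero-atoms, waters and alternate locations are
#' dropped with a warning.  Chains are ordered along the fibril stacking
#' axis: the principal axis of the chain CA centroids, with chains sorted by
#' ascending centroid projection (PDB deposition order is not trusted).
#'
#' @param path Path to a PDB file.
#' @return A `fibril_template`.
#' @export
read_template <- function(path) {
  if (!file.exists(path)) {
    stop("template file not found: ", path, call. = FALSE)
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  atoms <- pdb$atom
  n_het <- sum(atoms$type != "ATOM")
  if (n_het > 0) {
    warning("dropping ", n_het, " non-ATOM record(s) (hetero atoms/waters)",
            call. = FALSE)
    atoms <- atoms[atoms$type == "ATOM", , drop = FALSE]
  }
  chains <- unique(atoms$chain)
  if (length(chains) < 4L) {
    stop_validation(
      "template '", path, "' has ", length(chains),
      " chains; at least 4 are required"
    )
  }
  per_chain <- lapply(chains, function(ch) {
    a <- atoms[atoms$chain == ch, , drop = FALSE]
    resno <- sort(unique(a$resno))
    ca <- a[a$elety == "CA", , drop = FALSE]
    if (!all(resno %in% ca$resno)) {
      stop_validation(
        "template '", path, "' chain ", ch, ": residue(s) without CA"
      )
    }
    ca <- ca[match(resno, ca$resno), , drop = FALSE]
    cb <- a[a$elety == "CB", , drop = FALSE]
    cb <- cb[match(resno, cb$resno), , drop = FALSE]
    seq1 <- paste(bio3d::aa321(ca$resid), collapse = "")
    list(
      resno = resno,
      seq = seq1,
      ca = as.matrix(ca[, c("x", "y", "z")]),
      cb = as.matrix(cb[, c("x", "y", "z")])
    )
  })
  lens <- vapply(per_chain, function(x) length(x$resno), 1L)
  if (length(unique(lens)) != 1L) {
    stop_validation(
      "template '", path, "' chains differ in length: ",
      paste(lens, collapse = ", ")
    )
  }
  seqs <- vapply(per_chain, `[[`, "", "seq")
  if (length(unique(seqs)) != 1L) {
    stop_validation(
      "template '", path, "' layers do not share the same residue ordering"
    )
  }
  # Geometric stacking order: ascending projection of chain CA centroids on
  # the first principal axis of the centroids.  Axis sign is fixed so the
  # first file-order chain projects lower than the last (determinism).
  cents <- t(vapply(per_chain, function(x) colMeans(x$ca), numeric(3)))
  cc <- sweep(cents, 2, colMeans(cents))
  axis <- svd(cc)$v[, 1]
  proj <- as.numeric(cc %*% axis)
  if (proj[1] > proj[length(proj)]) {
    proj <- -proj
  }
  ord <- order(proj)
  n_res <- lens[1]
  n_layers <- length(chains)
  ca <- array(NA_real_, c(n_layers, n_res, 3L))
  cb <- array(NA_real_, c(n_layers, n_res, 3L))
  for (k in seq_len(n_layers)) {
    ca[k, , ] <- per_chain[[ord[k]]]$ca
    cb[k, , ] <- per_chain[[ord[k]]]$cb
  }
  fibril_template(
    id = tools::file_path_sans_ext(basename(path)),
    template_seq = seqs[1],
    ca = ca, cb = cb
  )
}

#' Write a threaded model as a PDB file
#'
#' Writes the four chains of a [build_hetero_model()] result as a classic
#' fixed-column PDB with chain identifiers A-D in stacking order.  CA points
#' are written as `CA` atoms; side-chain centroids as pseudo-atoms named
#' `SC` (element C).  Occupancy is 1.00.  Re-reading the file reproduces the
#' coordinates to the 0.001 Angstrom PDB precision.
#'
#' @param model A `threaded_model`.
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  if (!inherits(model, "threaded_model") || length(model$chains) != 4L) {
    stop_validation("write_model expects a 4-chain threaded model")
  }
  chain_ids <- c("A", "B", "C", "D")
  xyz <- NULL
  elety <- character()
  resid <- character()
  resno <- integer()
  chain <- character()
  for (k in seq_along(model$chains)) {
    ch <- model$chains[[k]]
    res <- seq_chars(ch$seq)
    for (i in seq_along(res)) {
      xyz <- c(xyz, ch$ca[i, ])
      elety <- c(elety, "CA")
      resid <- c(resid, bio3d::aa123(res[i]))
      resno <- c(resno, i)
      chain <- c(chain, chain_ids[k])
      if (!is.na(ch$sc[i, 1])) {
        xyz <- c(xyz, ch$sc[i, ])
        elety <- c(elety, "SC")
        resid <- c(resid, bio3d::aa123(res[i]))
        resno <- c(resno, i)
        chain <- c(chain, chain_ids[k])
      }
    }
  }
  n <- length(elety)
  bio3d::write.pdb(
    pdb = NULL, file = path, xyz = xyz,
    type = rep("ATOM", n), eleno = seq_len(n), elety = elety,
    resid = resid, resno = resno, chain = chain,
    o = rep(1, n), b = rep(0, n), elesy = rep("C", n)
  )
  invisible(path)
}

#' Read a threaded-model PDB back into chain coordinate lists
#'
#' Round-trip companion of [write_model()]: returns, per chain, the sequence
#' and the CA / side-chain-centroid coordinate matrices.
#'
#' @param path PDB path written by [write_model()].
#' @return List of chains, each with `seq`, `ca`, `sc`.
#' @export
read_model <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  atoms <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  lapply(unique(atoms$chain), function(chid) {
    a <- atoms[atoms$chain == chid, , drop = FALSE]
    resno <- sort(unique(a$resno))
    ca_rows <- a[a$elety == "CA", , drop = FALSE]
    ca_rows <- ca_rows[match(resno, ca_rows$resno), , drop = FALSE]
    sc_rows <- a[a$elety == "SC", , drop = FALSE]
    sc_rows <- sc_rows[match(resno, sc_rows$resno), , drop = FALSE]
    list(
      seq = paste(bio3d::aa321(ca_rows$resid), collapse = ""),
      ca = as.matrix(ca_rows[, c("x", "y", "z")]),
      sc = as.matrix(sc_rows[, c("x", "y", "z")])
    )
  })
}
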