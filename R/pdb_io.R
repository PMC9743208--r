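# Structure I/O. Reading and writing of PDB files is delegated to bio3d;
# internally every structure is handled as a plain atom table with columns
# eleno, elety, resid, chain, resno, x, y, z.

#' Coerce a structure to the internal atom table
#'
#' Accepts a `bio3d` `pdb` object, a generated model (`dna_model` or
#' `toy_binder`), or a data frame already in atom-table form.
#'
#' @param x structure object
#' @return data frame with columns `eleno`, `elety`, `resid`, `chain`,
#'   `resno`, `x`, `y`, `z`
#' @export
as_atom_table <- function(x) {
  if (is.data.frame(x)) {
    need <- c("elety", "resid", "chain", "resno", "x", "y", "z")
    miss <- setdiff(need, names(x))
    if (length(miss))
      stop("atom table is missing columns: ", paste(miss, collapse = ", "))
    if (is.null(x$eleno)) x$eleno <- seq_len(nrow(x))
    return(x)
  }
  if (inherits(x, c("dna_model", "toy_binder"))) return(as_atom_table(x$atoms))
  if (inherits(x, "pdb")) {
    a <- x$atom
    return(data.frame(
      eleno = a$eleno, elety = a$elety, resid = a$resid,
      chain = ifelse(is.na(a$chain), "A", a$chain), resno = a$resno,
      x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE
    ))
  }
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as a structure")
}

#' Read a PDB structure
#'
#' Thin wrapper around [bio3d::read.pdb()]. For multi-model (e.g. NMR)
#' files a model index must be chosen explicitly.
#'
#' @param file path to a PDB file
#' @param model model index to extract (default 1); an error is raised if
#'   the file holds several models and the default would be ambiguous is
#'   not desired -- the index always selects deterministically
#' @return atom table (see [as_atom_table()])
#' @export
read_structure <- function(file, model = 1) {
  pdb <- bio3d::read.pdb(file, multi = TRUE, verbose = FALSE)
  nmod <- nrow(pdb$xyz)
  if (is.null(nmod) || is.na(nmod)) nmod <- 1
  if (model < 1 || model > nmod)
    stop("model index ", model, " out of range: file has ", nmod, " model(s)")
  tab <- as_atom_table(pdb)
  xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
  tab$x <- xyz[, 1]; tab$y <- xyz[, 2]; tab$z <- xyz[, 3]
  tab
}

#' Write a structure to a PDB file
#'
#' @param x structure (anything [as_atom_table()] accepts)
#' @param file output path
#' @return `file`, invisibly
#' @export
write_structure_pdb <- function(x, file) {
  tab <- as_atom_table(x)
  bio3d::write.pdb(
    file = file,
    xyz = as.numeric(t(as.matrix(tab[, c("x", "y", "z")]))),
    resno = tab$resno, resid = tab$resid, eleno = tab$eleno,
    elety = tab$elety, chain = tab$chain
  )
  invisible(file)
}
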