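# Small in-code builders shared across test files.

# a bare one-chain structure from residue names placed on a line; every
# residue gets a single C atom unless atoms are supplied
atoms_df <- function(chain, resno, resid, elety, x, y, z, insert = "") {
  data.frame(chain = chain, resno = resno, insert = insert, resid = resid,
             elety = elety, elesy = substring(trimws(elety), 1L, 1L),
             x = x, y = y, z = z, stringsAsFactors = FALSE)
}

two_atom_complex <- function(gap) {
  structure_from_atoms(rbind(
    atoms_df("A", 1L, "ALA", "CA", 0, 0, 0),
    atoms_df("B", 1L, "GLY", "CA", gap, 0, 0)))
}

corpus_df <- function(pmids, texts, tags = rep(list("AND"), length(pmids)),
                      dates = as.Date("2005-06-01") + seq_along(pmids)) {
  d <- data.frame(pmid = as.character(pmids), title = "t", body = texts,
                  text = paste("t", texts), pub_date = dates,
                  stringsAsFactors = FALSE)
  d$retrieved_by <- tags
  d
}
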