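#' Dependency label inventory
#'
#' The 72 syntactic dependency labels the encoder's type lookup table covers:
#' the ClearNLP-style labels emitted by general-English parsers plus the
#' Universal Dependencies labels that commonly co-occur in converted
#' treebanks. Labels outside the inventory are mapped to the generic
#' \code{"dep"} row (unspecified dependency), so the table stays at 72 rows.
#'
#' @return character vector of length 72.
#' @export
dep_label_inventory <- function() {
  c(
    # ClearNLP / English parser labels
    "acl", "acomp", "advcl", "advmod", "agent", "amod", "appos", "attr",
    "aux", "auxpass", "case", "cc", "ccomp", "compound", "conj", "csubj",
    "csubjpass", "dative", "dep", "det", "dobj", "expl", "intj", "mark",
    "meta", "neg", "nmod", "npadvmod", "nsubj", "nsubjpass", "nummod",
    "oprd", "parataxis", "pcomp", "pobj", "poss", "preconj", "predet",
    "prep", "prt", "punct", "quantmod", "relcl", "root", "xcomp",
    # Universal Dependencies additions
    "obj", "obl", "iobj", "nmod:poss", "acl:relcl", "aux:pass",
    "nsubj:pass", "csubj:pass", "obl:npmod", "obl:tmod", "compound:prt",
    "cc:preconj", "det:predet", "flat", "fixed", "goeswith", "list",
    "orphan", "reparandum", "vocative", "discourse", "clf", "cop",
    "dislocated", "nmod:tmod", "nmod:npmod", "advcl:relcl"
  )
}

# Reserved row for labels outside the inventory.
DEP_UNKNOWN_LABEL <- "dep"

#' Virtual edge label inventory
#'
#' The six undirected virtual edge labels injected into document subgraphs.
#'
#' @return character vector of length 6.
#' @export
virtual_label_inventory <- function() {
  c("NEXT-SENT", "TITLE", "COREF-sent", "COREF-to-title",
    "COREF-from-title", "KB-CTD")
}

#' Part-of-speech tag inventory
#'
#' 56 OntoNotes 5.0 Penn Treebank tags plus one reserved unknown tag
#' (\code{"<unk-pos>"}), giving the 57-row POS lookup table.
#'
#' @return character vector of length 57; the last entry is the unknown tag.
#' @export
pos_tag_inventory <- function() {
  c("$", "``", "''", ",", "-LRB-", "-RRB-", ".", ":", "ADD", "AFX", "CC",
    "CD", "DT", "EX", "FW", "GW", "HYPH", "IN", "JJ", "JJR", "JJS", "LS",
    "MD", "NFP", "NN", "NNP", "NNPS", "NNS", "PDT", "POS", "PRP", "PRP$",
    "RB", "RBR", "RBS", "RP", "SYM", "TO", "UH", "VB", "VBD", "VBG", "VBN",
    "VBP", "VBZ", "WDT", "WP", "WP$", "WRB", "XX", "_SP", "NIL", "EMO",
    "URL", "X", "SP", "<unk-pos>")
}

# Character inventory for the character-level encoder: 84 printable
# characters plus one unknown slot = 85 rows.
char_inventory <- function() {
  ch <- c(letters, LETTERS, as.character(0:9),
          strsplit("-.,;:!?'\"()[]{}/\\%$&*+=<>@#_|~^` ", "")[[1]])
  ch <- unique(ch)
  length(ch) <- 84L
  ch[is.na(ch)] <- paste0("<pad", seq_len(sum(is.na(ch))), ">")
  c(ch, "<unk-char>")
}

map_dep_label <- function(labels) {
  inv <- dep_label_inventory()
  out <- ifelse(labels %in% inv, labels, DEP_UNKNOWN_LABEL)
  out
}

map_pos_tag <- function(tags) {
  inv <- pos_tag_inventory()
  ifelse(tags %in% inv, tags, "<unk-pos>")
}
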