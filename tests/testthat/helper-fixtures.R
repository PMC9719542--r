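# Programmatic fixtures written to tempfiles.

write_string_edges <- function(rows, sep = "\t") {
  path <- tempfile(fileext = ".tsv")
  header <- paste("protein1", "protein2", "combined_score", sep = sep)
  writeLines(c(header, vapply(rows, function(r) {
    paste(r[[1]], r[[2]], r[[3]], sep = sep)
  }, character(1))), path)
  path
}

toy_edge_rows <- function() {
  list(list("A", "B", 900), list("A", "C", 400), list("B", "C", 150),
       list("C", "D", 700), list("D", "E", 950))
}

k4_network <- function() {
  pairs <- utils::combn(letters[1:4], 2)
  interaction_network(pairs[1, ], pairs[2, ])
}

sort_faces <- function(df) {
  df <- df[order(df$v1, df$v2, df$v3), c("v1", "v2", "v3", "orientation")]
  rownames(df) <- NULL
  df
}

# Rebuild a complex with one face row removed (skeleton untouched).
build_without_face <- function(cx, drop) {
  faces <- cx$faces[-drop, , drop = FALSE]
  rownames(faces) <- NULL
  if (nrow(faces)) {
    idx <- rep(seq_len(nrow(faces)), 3L)
    cx$edge_faces <- split(idx, c(faces$e12, faces$e13, faces$e23))
    cx$vertex_faces <- split(rep(seq_len(nrow(faces)), 3L),
                             c(faces$v1, faces$v2, faces$v3))
  } else {
    cx$edge_faces <- list()
    cx$vertex_faces <- list()
  }
  cx$faces <- faces
  cx
}
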