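# Small named fixture graphs built in code.

two_triangles_bridge <- function() {
  ppi_graph(data.frame(a = c("a", "a", "b", "c", "d", "d", "e"),
                       b = c("b", "c", "c", "d", "e", "f", "f")))
}

path_graph <- function(nodes) {
  ppi_graph(data.frame(a = nodes[-length(nodes)], b = nodes[-1]))
}

star_graph <- function(center = "c", leaves = c("l1", "l2", "l3")) {
  ppi_graph(data.frame(a = rep(center, length(leaves)), b = leaves))
}

toy_id_map <- function() {
  id_map(alias = c("TP53", "trp53", "MDM2", "CDKN1A"),
         canonical = c("7157", "7157", "4193", "1026"))
}
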