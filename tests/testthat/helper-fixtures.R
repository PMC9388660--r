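# Shared in-code fixtures: tiny graphs, hand-built statistic objects, and a
# writer for minimal TAB3-style evidence files.

path_graph <- function(nodes = c("A", "B", "C", "D", "E")) {
  g <- igraph::make_ring(length(nodes), circular = FALSE)
  igraph::V(g)$name <- nodes
  g
}

complete_graph <- function(n, prefix = "K") {
  g <- igraph::make_full_graph(n)
  igraph::V(g)$name <- paste0(prefix, seq_len(n))
  g
}

# Evidence rows as read_interaction_table() would return them.
evidence_df <- function(a, b, org_a = 9606L, org_b = 9606L,
                        pub = "PUBMED:1", sys = "Two-hybrid",
                        type = "physical") {
  data.frame(interactor_a = toupper(a), interactor_b = toupper(b),
             organism_a = org_a, organism_b = org_b,
             publication_id = pub, experimental_system = sys,
             experimental_system_type = type, stringsAsFactors = FALSE)
}

write_tab3_fixture <- function(rows, path = tempfile(fileext = ".tsv")) {
  header <- paste("Official Symbol Interactor A",
                  "Official Symbol Interactor B",
                  "Experimental System", "Experimental System Type",
                  "Publication Source",
                  "Organism ID Interactor A", "Organism ID Interactor B",
                  sep = "\t")
  writeLines(c(paste0("#", header), rows), path)
  path
}

# Pass a generator's file-layout records through the reader (via a temp
# file), yielding parsed evidence records.
as_records <- function(records) {
  path <- tempfile(fileext = ".tsv")
  con <- file(path, "w")
  writeLines(paste0("#", paste(colnames(records), collapse = "\t")), con)
  write.table(records, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  close(con)
  read_interaction_table(path)
}

# Hand-built statistic containers for filter-rule tests that need full
# control over observed and expected values.
make_stats <- function(genes, membership, n_communities,
                       seed_genes = character(), radius = 2L) {
  present <- intersect(seed_genes, genes)
  structure(list(
    table = data.frame(gene = genes, membership_number = membership,
                       membership_proportion = membership / n_communities,
                       is_seed = genes %in% seed_genes,
                       stringsAsFactors = FALSE),
    seeds = structure(list(genes = seed_genes, present = present,
                           missing = setdiff(seed_genes, present)),
                      class = "seed_list"),
    n_communities = n_communities, radius = radius),
    class = "community_stats")
}

make_null <- function(genes, mean, sd, seed_set_size = 2L,
                      replicates = 1000L, radius = 2L) {
  structure(list(
    table = data.frame(gene = genes, mean = mean, sd = sd,
                       stringsAsFactors = FALSE),
    replicates = replicates, seed_set_size = seed_set_size,
    radius = radius, rng_seed = 1L, method = "monte-carlo"),
    class = "null_summary")
}
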