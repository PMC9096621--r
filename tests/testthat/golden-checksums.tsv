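file	md5
clusters.bed	9e817278e0ef603072de03c57725b8b4
de_clusters.tsv	159aae0e65c5e02840ac181e98e3cd01
de_genes.tsv	6efcc8887db2ba073015ec4844b70b28
deg_categories.tsv	7ff4f8f6d82f715faae27f80622311ce
deg_dmp_per_gene.tsv	85b6ce7bec54ee853f1e7095ff654f03
dm_clusters.tsv	bd57f19d1966b8267049f1f3dc49d671
dm_promoters.tsv	15ef0f4431ac83a415888e5c5caed435
dmp.bed	3e21bb54806cdc9b684f9b3936545148
integration.json	4c302149fcb48958a927fa2a9b0cbe5b
motif_curves.tsv	2e7db808e6893b1302166c73f89b3604
motif_enrichment.json	19a4a0091f110b3a1bc76cc798fa40ad
srna_location_strata.tsv	9541b7a398009793a3b33304e7c83995
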