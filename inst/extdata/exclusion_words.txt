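# Default exclusion list: database prefixes/suffixes and bookkeeping tokens
# commonly used to name gene-set collections. One word per line; lines
# starting with '#' are comments. Informative biological words (pathway,
# signaling, regulation, ...) are deliberately NOT excluded.
kegg
reactome
hallmark
wikipathways
biocarta
pid
go
gobp
gocc
gomf
hp
wp
sa
st
module
msigdb
gsea
geneset
genesets
dn
up
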