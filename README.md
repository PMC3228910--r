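# litcooc

Co-occurrence mining of gene/protein interactions from literature abstracts.

## The problem

Given a corpus of biomedical abstracts `D = {d_1, …, d_n}`, a gene dictionary
mapping surface names to gene identifiers, and a dictionary of biointeraction
trigger words (`binds`, `inhibits`, `phosphorylates`, …), find candidate
interactions between pairs of bioentities and grade how strongly the text
supports each one. For two entities `a`, `b` co-occurring in sentence `s`,
the pair is assigned a **confidence type**:

| Type | Evidence |
|------|----------|
| 1 | a trigger word occurs strictly *between* the names of `a` and `b` in `s` |
| 2 | a trigger word occurs somewhere in `s`, but not between the names |
| 3 | `a` and `b` share sentence `s`, with no trigger word in it |
| 4 | `a` and `b` occur in the same abstract but never in the same sentence |

Lower type = stronger evidence; type 1 ⊆ type ≤2 ⊆ type ≤3 ⊆ type ≤4 gives a
precision/recall trade-off dial. Sentences naming **four or more distinct
bioentities** are excluded as too complex to pair reliably (they still
contribute to abstract-level type 4). Pairs are annotated with user-supplied
concepts (e.g. `aggregation`) found in the same sentence (types 1–3) or the
same abstract (type 4). Negation is deliberately ignored: "A does *not* bind
B" is still reported as type 1, because the co-occurrence itself is the
signal being mined.

## Worked example

```r
library(litcooc)

rec <- abstract_record("100001", "",
  paste("Deposits of Abeta proteins were found where alpha-synuclein",
        "accumulates, and each interacts with tau in transgenic mice."))
lex <- gene_lexicon(c("351", "6622", "4137"), c("APP", "SNCA", "MAPT"),
                    list("Abeta", "alpha-synuclein", "tau"))

tg <- tag_abstract(rec, lex, interaction_lexicon("interacts"))
pairs <- extract_sentence_pairs(tg)
pairs[, c("pmid", "term1", "term2", "type")]
#> # A tibble: 3 × 4
#>   pmid   term1           term2            type
#>   <chr>  <chr>           <chr>           <int>
#> 1 100001 abeta           alpha-synuclein     2
#> 2 100001 abeta           tau                 1
#> 3 100001 alpha-synuclein tau                 1
```

`interacts` sits between each entity and `tau` (type 1) but not between
`Abeta` and `alpha-synuclein`, which only share the sentence with it
(type 2).

The full pipeline on files:

```r
corpus <- read_corpus("corpus.txt", format = "medline")   # or "pubmed-xml"
glex   <- load_gene_dictionary("gene_lexicon.tsv")
ilex   <- load_interaction_terms()                        # shipped defaults
cons   <- load_concepts(c("aggregation", "phosphorylation"))

cooc <- extract_cooccurrences(corpus, glex, ilex, cons)
s    <- summarize_pairs(cooc)
net  <- build_network(s, network_filter(max_type = 2), glex)
export_network(net, "network.graphml", "graphml")         # also "sif", "tsv"
```

## Evaluation bench

`load_gold()` / `filter_gold()` read a gold-standard interaction table and
drop self-interactions and non-gene symbols; `pool_truth()` unions the
filtered gold with expert-confirmed novel predictions on `(pmid, pair)` keys;
`score_predictions()` reports cumulative recall/precision at each type
threshold; `stratify_recall()` re-computes recall on nested strata (both
entities in dictionary ⊇ both detected ⊇ evidence sentence not complex) to
separate entity-recognition failures from pairing failures.

## Synthetic fixtures

`fixture_config()` + `generate_corpus()` deterministically plant pairs of
known type into a MEDLINE-format corpus with matching lexicons and a
truthful gold table, so the whole pipeline is testable offline;
`two_hub_config()` is a preset with two hub entities of known degree. The
same seed gives byte-identical files.

## Command line

```sh
Rscript inst/cli/litcooc.R extract  --corpus corpus.txt --gene-dictionary g.tsv --out-dir out/
Rscript inst/cli/litcooc.R network  --cooccurrences out/cooccurrences.tsv --out net.graphml --max-type 2
Rscript inst/cli/litcooc.R eval     --cooccurrences out/cooccurrences.tsv --gold gold.tsv --out-dir out/
Rscript inst/cli/litcooc.R simulate --seed 7 --out-dir fixture/
```

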