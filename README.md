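# docgraphre

Document-level chemical–disease relation (CDR) extraction in R: a complete,
desk-scale implementation of a BiLSTM + multihead-attention +
graph-convolution pipeline over a document-level dependency graph.

## The problem

Chemical-induced disease (CID) relations in the biomedical literature are
annotated at the **document** level: a chemical concept and a disease
concept (both normalised to MeSH identifiers) are related for an abstract
as a whole, and the evidence may sit inside one sentence or be spread
across several. Classifiers that only see single sentences systematically
miss the cross-sentence cases. This package is for text-mining researchers
and methods students who want a fully inspectable, dependency-light
implementation of a document-level extraction pipeline — every stage, from
corpus parsing to backpropagation, is plain R that can be read, tested and
perturbed.

The pipeline:

1. **Corpus IO** — PubTator-format abstracts (title/abstract lines,
   offset-based entity mentions with MeSH ids, CID relation lines) and
   CoNLL-U dependency parses; mentions are aligned to token spans.
2. **Candidate construction** — one candidate instance per
   (chemical, disease) concept pair and document: *intrasentence* when the
   concepts co-occur in a sentence (nearest co-sentential mention pair is
   chosen), otherwise *intersentence* (mention pair with the smallest
   sentence distance; pairs more than `max_sentence_distance = 3`
   sentences apart are dropped).
3. **Document graph** — nodes are all tokens of the abstract; edges are
   the per-sentence syntactic dependencies, one edge between the
   dependency roots of adjacent sentences, and a self-loop on every node.
4. **Classifier** — per-token features `w_i = [w_ctx; w_pos; w_dist]`
   (contextual vector ⊕ POS embedding ⊕ signed clipped distances to the
   chemical and to the disease mention) are encoded by a BiLSTM
   (`h_t = o_t ⊙ tanh(c_t)`, standard gates); two branches follow:
   self-attention (`softmax(QK'/√d)V`, multihead or one of three
   single-head scoring functions) and a GCN over the document graph
   (`h_i^(l) = ρ(d_i^{-1} Σ_j A_ij W h_j^(l-1) + b)` with symmetric
   binary `A`, unit diagonal). Max-pooled sentence, chemical-entity,
   disease-entity and attention vectors are concatenated and fed to a
   two-layer rectified perceptron with a softmax over
   {no relation, CID}.
5. **Training/evaluation** — Adam on minibatch cross-entropy with early
   stopping on development merged F; micro precision / recall / F at the
   intrasentence, intersentence and merged (document) levels.

Because the full-scale inputs (BioCreative V CDR corpus, a pretrained
contextual language model, an external parser) are deliberately out of
scope, the package ships a **synthetic corpus generator** that emulates
the corpus shape and plants a decision rule — a trigger token on the
dependency path between the two mentions — that is solvable through the
graph but *not* from bags of words. A deterministic hash embedder stands
in for the pretrained contextual model.

## Worked example

```r
library(docgraphre)
train_docs <- generate_corpus(synthetic_spec(n_docs = 150, seed = 1))
test_docs  <- generate_corpus(synthetic_spec(n_docs = 50,  seed = 2))
corpus_stats(train_docs)
#>   n_docs n_mentions n_relations n_intra n_inter n_instances positive_rate
#> 1    150        609          99     175     125         300          0.33

train_inst <- build_all(train_docs)
test_inst  <- build_all(test_docs)
ck <- train(train_inst, train_docs,
            model_config("test", seed = 1),
            training_config("test", seed = 1))
preds <- predict_relations(ck, test_inst, test_docs)
head(preds, 3)
#>   doc_id chemical_id disease_id level      prob
#> 3     10     D229408    D380725 intra 0.9736010
#> 4     10     D229408    D935295 intra 0.9717994
#> 6     11     D579670    D203839 inter 0.9526955

evaluate(preds, gold_pairs(test_docs), test_inst)
#>    level tp fp fn precision    recall f_measure
#> 1  intra 18  0  1 1.0000000 0.9473684 0.9729730
#> 2  inter 16  3  0 0.8421053 1.0000000 0.9142857
#> 3 merged 34  3  1 0.9189189 0.9714286 0.9444444
```

The model recovers almost all planted relations, including the
cross-sentence ones, from 150 training abstracts; a bag-of-words logistic
baseline on the same corpus stays far below (the trigger counts per
document are matched between classes by construction, see
`bow_baseline()` and the methods vignette).

Every table above is a `data.frame`; `prob` is the softmax CID
probability (threshold 0.5), and the three evaluation rows are micro
precision/recall/F at the intrasentence, intersentence and merged
document levels (gold pairs unreachable by candidate construction count
as false negatives).

## Command line

```sh
Rscript inst/cli/docgraphre simulate   --out corpus/ --n-train 300 --seed 1
Rscript inst/cli/docgraphre preprocess --pubtator corpus/train.pubtator \
                                       --conllu corpus/train.conllu
Rscript inst/cli/docgraphre train      --pubtator corpus/train.pubtator \
                                       --conllu corpus/train.conllu --out ck.rds
Rscript inst/cli/docgraphre evaluate   --checkpoint ck.rds \
                                       --pubtator corpus/test.pubtator \
                                       --conllu corpus/test.conllu
Rscript inst/cli/docgraphre ablate     --train-pubtator corpus/train.pubtator \
                                       --train-conllu corpus/train.conllu \
                                       --test-pubtator corpus/test.pubtator \
                                       --test-conllu corpus/test.conllu --grid gcn
```

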