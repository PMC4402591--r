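# Published per-drug precision/recall of knowledge-driven (kd) vs SVM (svm)
# sentence-level drug-SE extraction for the ten SIDER drugs with the most
# side effects, evaluated against held-out label-derived pairs.
# drug	kd_precision	kd_recall	svm_precision	svm_recall
fluoxetine	0.370	0.425	0.178	0.838
tacrolimus	0.315	0.519	0.140	0.961
risperidone	0.561	0.622	0.234	0.959
carbamazepine	0.341	0.627	0.118	0.896
ibuprofen	0.230	0.406	0.106	0.891
olanzapine	0.463	0.492	0.180	0.921
morphine	0.214	0.611	0.090	0.833
phenytoin	0.229	0.403	0.104	0.881
methotrexate	0.230	0.607	0.082	0.984
ciprofloxacin	0.397	0.377	0.121	0.836
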