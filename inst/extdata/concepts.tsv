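pattern	replacement
positive regulation	upregulated
negative regulation	downregulated
up regulation	upregulated
down regulation	downregulated
ppar alpha	ppar-alpha
pparα	ppar-alpha
pparalpha	ppar-alpha
increased	increase
increasing	increase
increases	increase
decreased	decrease
decreasing	decrease
decreases	decrease
activated	activation
activating	activation
inhibited	inhibition
inhibiting	inhibition
induced	induction
inducing	induction
signalling	signaling
tumour	tumor
fibroses	fibrosis
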