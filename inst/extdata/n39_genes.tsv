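symbol	title
ADK	adenosine kinase
AP2B1	adaptor-related protein complex 2, beta 1 subunit
AVL9	AVL9 homolog (S. cerevisiase)
CANX	calnexin
DBT	dihydrolipoamide branched chain transacylase E2
DHRS7	dehydrogenase/reductase (SDR family) member 7
DONSON	downstream neighbor of SON
FAM190B	family with sequence similarity 190, member B
FGFR1	fibroblast growth factor receptor 1
FOXN3	forkhead box N3
FZD5	frizzled family receptor 5
GGH	gamma-glutamyl hydrolase (conjugase, folylpolygammaglutamyl hydrolase)
GM2A	GM2 ganglioside activator
IGFBP5	insulin-like growth factor binding protein 5
ITSN2	intersectin 2
LAMC1	laminin, gamma 1 (formerly LAMB2)
LIFR	leukemia inhibitory factor receptor alpha
METTL7A	methyltransferase like 7A
MT1F	metallothionein 1F
MT1G	metallothionein 1G
MT1P2	metallothionein 1 pseudogene 2
MT1X	metallothionein 1X
MT2A	metallothionein 2A
NAB1	NGFI-A binding protein 1 (EGR1 binding protein 1)
NCOA1	nuclear receptor coactivator 1
NCOR1	nuclear receptor corepressor 1
PAPOLA	poly(A) polymerase alpha
PPME1	protein phosphatase methylesterase 1
PPP1R13L	protein phosphatase 1, regulatory subunit 13 like
PRKAR2A	protein kinase, cAMP-dependent, regulatory, type II, alpha
RABEP1	rabaptin, RAB GTPase binding effector protein 1
RBBP8	retinoblastoma binding protein 8
SGPL1	sphingosine-1-phosphate lyase 1
SIRT1	sirtuin 1
SNX2	sorting nexin 2
SREK1	splicing regulatory glutamine/lysine-rich protein 1
TAF1B	TATA box binding protein (TBP)-associated factor, RNA polymerase I, B, 63 kDa
TMED5	transmembrane emp24 protein transport domain containing 5
ZMIZ2	zinc finger, MIZ-type containing 2
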