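drug,factor
levodopa,1
levodopa_cr,0.75
duodopa,1.11
pramipexole,100
ropinirole,20
rotigotine,30
apomorphine,10
piribedil,1
bromocriptine,10
cabergoline,67
pergolide,100
selegiline_oral,10
selegiline_sublingual,80
rasagiline,100
amantadine,1
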