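# acetaminophen heavy-atom skeleton, hand-transcribed
# C1 methyl, C2 carbonyl C, O3 carbonyl O, N4 amide N, C5-C11 ring + phenol O9
name Acetaminophen
C1 C2
C2 O3
C2 N4
N4 C5
C5 C6
C5 C11
C6 C7
C7 C8
C8 O9
C8 C10
C10 C11
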