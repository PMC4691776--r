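code,term,group
N04y0,Seropositive rheumatoid arthritis,1
N0455,Erosive rheumatoid arthritis,1
N040.,Rheumatoid arthritis,2
N0401,Rheumatoid arthritis of knee,2
N0402,Rheumatoid arthritis of shoulder,2
N0403,Rheumatoid arthritis of wrist,2
N0430,Rheumatoid lung disease,3
N043.,Felty's syndrome,3
N0454,Seronegative rheumatoid arthritis,4
Nyu12,Other specified inflammatory polyarthropathy,4
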