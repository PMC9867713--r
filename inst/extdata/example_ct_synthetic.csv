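sample,gene,replicate,Ct
CTRLsh,GAPDH,1,18.12
CTRLsh,GAPDH,2,18.05
CTRLsh,GAPDH,3,18.21
CTRLsh,GPC4,1,23.90
CTRLsh,GPC4,2,24.11
CTRLsh,GPC4,3,24.02
GPC4sh5,GAPDH,1,18.30
GPC4sh5,GAPDH,2,18.18
GPC4sh5,GAPDH,3,18.26
GPC4sh5,GPC4,1,25.52
GPC4sh5,GPC4,2,25.60
GPC4sh5,GPC4,3,25.41
GPC4sh2,GAPDH,1,17.95
GPC4sh2,GAPDH,2,18.07
GPC4sh2,GAPDH,3,18.00
GPC4sh2,GPC4,1,25.71
GPC4sh2,GPC4,2,25.80
GPC4sh2,GPC4,3,25.68
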