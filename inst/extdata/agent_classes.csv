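agent,class
pembrolizumab,PD-1
nivolumab,PD-1
cemiplimab,PD-1
atezolizumab,PD-L1
durvalumab,PD-L1
avelumab,PD-L1
ipilimumab,CTLA4
carboplatin,chemotherapy
cisplatin,chemotherapy
pemetrexed,chemotherapy
paclitaxel,chemotherapy
docetaxel,chemotherapy
gemcitabine,chemotherapy
fluorouracil,chemotherapy
oxaliplatin,chemotherapy
capecitabine,chemotherapy
erlotinib,oncogene TKI
osimertinib,oncogene TKI
alectinib,oncogene TKI
tamoxifen,hormonal
letrozole,hormonal
anastrozole,hormonal
leuprolide,hormonal
bevacizumab,other
trastuzumab,other
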