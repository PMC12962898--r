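element,class
Quercetin,flavonoid
Kaempferol,flavonoid
Luteolin,flavonoid
Apigenin,flavonoid
Naringenin,flavonoid
Isorhamnetin,flavonoid
Baicalein,flavonoid
Wogonin,flavonoid
Genistein,flavonoid
Rutin,flavonoid
Hesperetin,flavonoid
Catechin,flavonoid
Epicatechin,flavonoid
Myricetin,flavonoid
Chrysin,flavonoid
Galangin,flavonoid
Fisetin,flavonoid
Morin,flavonoid
Daidzein,flavonoid
Taxifolin,flavonoid
Beta-sitosterol,phytosterol
Stigmasterol,phytosterol
Ursolic acid,triterpenoid
Oleanolic acid,triterpenoid
Ferulic acid,phenolic acid
Vanillic acid,phenolic acid
Caffeic acid,phenolic acid
Chlorogenic acid,phenolic acid
Gallic acid,phenolic acid
Salvianolic acid B,phenolic acid
Paeoniflorin,monoterpene glycoside
Berberine,alkaloid
Curcumin,curcuminoid
Resveratrol,stilbene
Emodin,anthraquinone
Rhein,anthraquinone
Astragaloside IV,triterpenoid saponin
Ginsenoside Rg1,triterpenoid saponin
Glycyrrhizin,triterpenoid saponin
Tanshinone IIA,diterpenoid quinone
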