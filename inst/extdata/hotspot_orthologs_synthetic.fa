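>HUMAN_SMAD4_SYNTHETIC
NYAPCRLMFSFQPGGRYNNKTSCHEFMVKWAQEPEDCFYGQDWPGCRHIVHLNQYGLHWIVMQKEMYIARLPTDHGLPGEHMPFFWSNPGWARISFVFMWVQRADEKARCDEVTTFDARVDDCFWSSHSRHNVIERPYLDDPLWGDIRIAYIYEIFCKAHNDFCQFTHQKTFMECAQRTEWRRYGDKQNFVNWREEGRQFFQGWACWNYTRVMQHVHYDGNNIYFPCQFHIYVCDQFWWCDPCFHEKNCRNYIRLIQIICSDTYVRGLEDHQWTFGIDGFACDKEQVFLRCLEGGANDHTIALFSDFCRLYVVFLSSIFFYQVVNKVTEQTLPQLSGQVGEGSNNMAVHQRFHGSKTYFFRNHGYPAGFDYQIKYWEATH
>MOUSE_Smad4_SYNTHETIC
NYAPCRLMFSFQPGGRYNNKTSCHEFMVKWAQEPEDCFYGQDWPGCRHIVHLNQYGLHWIVMQKEMYIARLPTDHGLPGEHMPFFWSNPGWARISFVFMVQRADEKARCDEVTTFDARVDDCFWSSHSRHNVIERPYLDDPLWGDIRIAYIYEIFCKAHNDFCQFTHQKTFMECAQRTEWRRYGDKQNFVNWREEGRQFFQGWACWNYTRVMQHVHYDGNNIYFPCQFHIYVCDQFWWCDPCFHEKNCRNYIRLIQIICSDTYVRGLEDHQWTFGIDGFACDKEQVFLRCLEGGANDHTIALFSDFCRLYVVFLSSIFFYQVVNKVTEQTLPQLSGQVGEGSNNMAVHQRFHGSKTYFFRNHGYPAGFDYQIKYWEATH
>HUMAN_PIK3CA_SYNTHETIC
FFFAVDYSETYWQNPTWQLPLQECFACEVVNDWWTIYDVVCYGSCQKKLEKSSYPQKWLVWDWIEDYCITTNRHMWTSMPEGTCWCPTLFEWPVWYEPFCFWIQSRGRCHKWRDDTKTSFLSVIHKFRGHIMDWRYWNGWMDYAGMVKNFGFYNKYPGHMWYIPDPLCWMIIEGDRPLMIDNMMQCNFIVLEKIPYYWRMFDDVFFPFLNKKVIDAIDHKGLCNKPKFLQKKCWCNECIVHVQFCYRHPSNQSDMLRCRTTGKNRQRFLSYSPHIVFLKRDINDIPSSEKQEVSPSEMSWFRQESLTEFNGMLVERFCHSEGDSGHTPGQMHNHDKAHNIHKVTQNFIQWQLCDFILSHKKKYQSDATMYWGPMHHYEYASAHHMPRAPKMSIDKTSKMNMLKKCNMVFELNWKWIYNRTKNIRSESYMERPCRCFINCVIVNFENVCCCTHCTKHEIHRPKIKCHYHSIVWDNDGLRSNRRDDTPFTERTMLRHEVRRKGGVYSLIFPTPYLNQEHKDVGEVTKAYMCWKDWQLKIHLESQPTEAMKICNGYTVMKEDH
>MOUSE_Pik3ca_SYNTHETIC
FFFAVDYSETYWQNPTWQLPLQECFACEVVNDWWTIYDVVCYGSCQKKLEKSSYPQKWLVWDWIEDYCITTNRHMWTSMPEGTCWCPTLFEWPVWYEPFCFWIQSRGRCHKWRDDTKTSFLSVIHKFRGHIMDWRYWNGWMDYAGMVKNFGFYNKYPGHMWYIPDPLCWMIIEGDRPLMIDNMMQCNFIVLEKIPYYWRMFDDVFFPFLNKKVIDAIDHKGLCNKPKFLQKKCWCNECIVHVQFCYRHPSNQSDMLRCRTTGKNRQRFLSYSPHIVFLKRDINDIPSSEKQEVSPSEMSWFRQESLTEFNGMLVERFCHSEGDSGHTPGQMHNHDKAHNIHKVTQNFIQWQLCDFILSHKKKYQSDATMYWGPMHHYEYASAHHMPRAPKMSIDKTSKMNMLKKCNMVFELNWKWIYNRTKNIRSESYMERPCRCFINCVIVNFENVCCCTHCTKHEIHRPKIKCHYHSIVWDNDGLRSNRRDDTPFTERTMLRHEVRRKGGVYSLIFPTPYLNQEHKDVGEVTKAYMCWKDWQLKIHLESQPTEAMKICNGYTVMKEDH
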