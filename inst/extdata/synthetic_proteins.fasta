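>SP0001
RCQRLRYGLYACLMWCAYCFHWLVREHQSVSPWKHDSADAWTATNNDESIQPGFQAIMVP
GVQGSCPLPRSHFSKPHTIMGCCGQSPYYRNFITTPPHYARRMSKVIL
>SP0002
MMSHTVHDKKRHYAGRWKTYVKECITCCLIREPYGCRNIHQIPSCQYMKPMPLNCPRDDL
DCEKEIYVNGIIYECGPICCSSMCIRWFVLPLAFGGMTNSLVKNMWFPMANEGPSGNPGS
AECVMDSMSPMLPCFYNPGMSECMKTRCNYFCVPYWCELC
>SP0003
WNNDLHLSPANPFSNSVRNHNCIKCSFLSNWYHPNGCAFCPYGTWADHCGMYHVRIYSPD
QLMNEGDCEHSSYHEWLKSPRLQYFLMTGATKTYHGCNICRAPCSVKLHGKECAPCVFQP
RFAW
>SP0004
MSSFTDWCAGCHCKGRCCGIDSCLAEMSLNQFFMLCYSDPCFTYHVGLCEQSDDQQDGGQ
WVHCVSCTNPHVNSWYFLKWPEGK
>SP0005
VCWLWGCSAFVDFPIGPSCPFECWKCWGCIPGFNCGNKEYVCTQSYLGVPETDCSMFPRA
FPMIQPNNWPQCCCYGWIEPSSGNRGFITPASPTSSKKGYQTPLAALRNVDAEFMNSLFG
IGFLIPLFLFQNV
>SP0006
YCPFNLKPRCQGDRLNGPGMRCFVRNCKVFQFHAYPYWQFLPCLNIWNEPIMDVGLICHC
CPGGHFWIYNECCRMKCWVSRMYWLIFPRIRPGNKWWHRERHGSQPTCHNEHDDKDAAYC
LNQTVYKMYWDSIYHGCHPCGMCAYARCSQQYDDMDCHP
>SN0001
RCPHKEVEYWFNNFNGHNFYMQSQYDCNGQKCCAGCGDGLCKPQHRYCTVDPNEHKVFNT
HLRCPYLYARHGIWDFMIV
>SN0002
WCVLREMYPYTQTYFFDVVHLQKKYKDSRDCLCPYIGNEKIYYTTAPGETAAEQWEKFLM
AYYTDCIGTMNDITKCSPDILISKQQVRRLRCVDYDFTGLLQPDFHKSELCMTMGWEHWT
DVWEENDMCVDVNMCPSGVLPFFFVEHTH
>SN0003
WCIIEKMCAYAFCEKNYQMDYIKQSFPVACVGERHVQNCHCWEDKRWGKQPCMYGRYCEE
LAKSSCYNRCYCTNHNNDYPDRQDLQVKTWQKYSDEVTDYSYNIVTNTDMCSSCMPHDKN
HYLSFGCILEWCAVNYMNVFNLILCGEK
>SN0004
RLDRWWDCLAMAMEPGSTLMLYPRIDYRCEVLLLRFVYTNHRYADKVNILCVCRPIAVQE
WPTCHTV
>SN0005
NQMPEVLTAHVRTFTSTIDRCQHKYRSSGLPWPYKHSGLRRFSIKTKHHCRSQDNDHCST
EPKRKVAMDEWSWYMDSHI
>SN0006
KIDPTNHLWYNTTVYLQGWYPRDGNNTHRPLWEISNFREHSCELPFNVDMWLHDWEIRHL
MGKDKAFWEFSHGPDMIWGNCNKCPLQ
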